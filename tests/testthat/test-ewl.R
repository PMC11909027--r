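test_that("resting-window detector finds flat plateaus and breaks ties early", {
  dt <- 5
  spikes <- function(n) 25 + 5 * rep(c(0, 1), length.out = n)
  # unique low plateau amid movement spikes
  tr <- make_trace(c(spikes(36), rep(20, 90), spikes(36)), dt = dt)
  w <- detect_resting_window(tr)
  an_start <- min(tr$time_s[tr$segment == "animal"])
  expect_gte(w$start_s, an_start + 36 * dt)
  expect_lte(w$end_s, an_start + (36 + 90) * dt)
  expect_equal(w$mean_rh_pct, 20)

  # constant trace: every window qualifies, earliest wins
  tr2 <- make_trace(rep(20, 120), dt = dt)
  w2 <- detect_resting_window(tr2)
  expect_equal(w2$start_s, min(tr2$time_s[tr2$segment == "animal"]))

  # two plateaus at 22% and 19%: the lower one wins
  tr3 <- make_trace(c(rep(22, 80), 21, 20.4, rep(19, 80)), dt = dt)
  w3 <- detect_resting_window(tr3)
  expect_equal(w3$mean_rh_pct, 19)
  o3 <- oracle_resting_window(tr3)
  expect_equal(w3$start_s, o3$start_s)

  # all movement, no flat stretch
  tr4 <- make_trace(spikes(120), dt = dt)
  expect_error(detect_resting_window(tr4), "no rest period")
  # animal segment too short for any rest period
  tr5 <- make_trace(rep(20, 30), dt = dt)
  expect_error(detect_resting_window(tr5), "shorter than")
})

test_that("detector agrees with the exhaustive all-windows scan on synthetic traces", {
  cfg <- sim_config(seed = 42, trace_noise_sd = 0.15)
  for (k in 1:12) {
    tr <- synth_flow_trace(cfg, true_mw_g_s = 4e-6 * k / 6,
                           seed = 1000 + k)
    w <- detect_resting_window(tr)
    o <- oracle_resting_window(tr)
    expect_equal(w$start_s, o$start_s)
    expect_equal(w$mean_rh_pct, o$mean)
  }
})

test_that("open-flow mass balance reproduces hand arithmetic", {
  # flow 0.2 L/min = 3.333 cm3/s; a 3e-6 g/cm3 rise gives 1e-5 g/s
  expect_equal(flow_l_min_to_cm3_s(0.2), 10 / 3)
  rh_b <- 2
  rh_a <- rh_b + 3e-6 / oracle_vd(30, 1)  # vapour-density rise of 3e-6
  tr <- make_trace(rep(rh_a, 120), baseline_rh = rh_b, baseline_s = 300)
  res <- compute_ewl(tr, list(flow_rate_l_min = 0.2))
  expect_equal(res$mw_g_s, 1e-5, tolerance = 1e-6)
  expect_equal(res$mw_g_h, res$mw_g_s * 3600)
  expect_true(res$valid)

  # no humidity rise -> zero flux
  tr0 <- make_trace(rep(2, 120), baseline_rh = 2, baseline_s = 300)
  res0 <- compute_ewl(tr0, list(flow_rate_l_min = 0.2))
  expect_equal(res0$mw_g_s, 0, tolerance = 1e-12)
})

test_that("baseline handling: symmetry, drift interpolation, invalid trials", {
  tr <- make_trace(rep(20, 120), baseline_rh = 2, baseline_s = 300)
  res <- compute_ewl(tr, list(flow_rate_l_min = 0.2))
  # swapping identical pre/post baselines changes nothing
  tr_sw <- tr
  tr_sw$segment[tr_sw$segment == "baseline_pre"] <- "tmp"
  tr_sw$segment[tr_sw$segment == "baseline_post"] <- "baseline_pre"
  tr_sw$segment[tr_sw$segment == "tmp"] <- "baseline_post"
  res_sw <- compute_ewl(tr_sw, list(flow_rate_l_min = 0.2))
  expect_equal(res_sw$vd_baseline_g_cm3, res$vd_baseline_g_cm3)
  expect_equal(res_sw$mw_g_s, res$mw_g_s)

  # drifting baseline: warn and interpolate linearly in time
  tr_dr <- tr
  post <- tr_dr$segment == "baseline_post"
  tr_dr$rh_pct[post] <- 4
  expect_warning(res_dr <- compute_ewl(tr_dr, list(flow_rate_l_min = 0.2)),
                 "drift")
  vd_pre <- oracle_vd(30, 2)
  vd_post <- oracle_vd(30, 4)
  t_pre <- mean(tr_dr$time_s[tr_dr$segment == "baseline_pre"])
  t_post <- mean(tr_dr$time_s[post])
  t_mid <- (res_dr$rest_start_s + res_dr$rest_end_s) / 2
  expect_equal(res_dr$vd_baseline_g_cm3,
               vd_pre + (vd_post - vd_pre) * (t_mid - t_pre) / (t_post - t_pre),
               tolerance = 1e-9)

  # chamber drier than baseline beyond tolerance -> flagged invalid
  tr_inv <- make_trace(rep(2, 120), baseline_rh = 6, baseline_s = 300)
  expect_warning(res_inv <- compute_ewl(tr_inv, list(flow_rate_l_min = 0.2)),
                 "invalid")
  expect_false(res_inv$valid)
  expect_lt(res_inv$mw_g_s, 0)
})

test_that("water flux is invariant to uniform time resampling", {
  cfg <- sim_config(seed = 5, trace_noise_sd = 0, movement_artifact_rate = 0)
  tr <- synth_flow_trace(cfg, true_mw_g_s = 5e-6)
  res5 <- compute_ewl(tr, list(flow_rate_l_min = 0.2))
  # resample each segment to a 2-s grid by linear interpolation
  segs <- lapply(split(tr, tr$segment), function(s) {
    t2 <- seq(min(s$time_s), max(s$time_s), by = 2)
    data.frame(time_s = t2,
               rh_pct = approx(s$time_s, s$rh_pct, t2)$y,
               temp_c = approx(s$time_s, s$temp_c, t2)$y,
               segment = s$segment[1])
  })
  tr2 <- do.call(rbind, segs)
  tr2 <- tr2[order(tr2$time_s), ]
  res2 <- compute_ewl(tr2, list(flow_rate_l_min = 0.2))
  expect_equal(res2$mw_g_s, res5$mw_g_s, tolerance = 0.01)
})

test_that("area-specific EWL and total resistance follow their defining algebra", {
  expect_equal(area_specific_ewl(1e-5, 20), 5e-7)
  expect_equal(area_specific_ewl(0, 20), 0)
  expect_equal(area_specific_ewl(1e-5, 40), area_specific_ewl(1e-5, 20) / 2)
  expect_error(area_specific_ewl(1e-5, 0), "positive")

  # hand calculation with the independently coded vapour-density oracle
  r <- total_resistance(30, 1e-5, 1e-7)
  expect_equal(r, (oracle_vd(30, 100) - 1e-5) / 1e-7, tolerance = 1e-10)
  expect_equal(r, 203.9, tolerance = 0.01)
  # no gradient -> zero resistance
  vds <- saturation_vapour_density(30)
  expect_equal(total_resistance(30, vds, 1e-7), 0)
  # halving the flux doubles the resistance
  expect_equal(total_resistance(30, 1e-5, 5e-8), 2 * r)
  expect_error(total_resistance(30, 1e-5, 0), "positive")
  expect_warning(rna <- total_resistance(20, 3e-5, 1e-7), "supersaturated")
  expect_true(is.na(rna))
})

test_that("trace and metadata validation catches malformed trials", {
  tr <- make_trace(rep(20, 120))
  expect_error(compute_ewl(tr, list(flow_rate_l_min = -1)), "positive")
  expect_error(compute_ewl(tr, list(flow_rate_l_min = 0.2, skin_temp_c = 50)),
               "15, 45")
  bad <- tr
  bad$time_s[5] <- bad$time_s[4]
  expect_error(compute_ewl(bad, list(flow_rate_l_min = 0.2)), "increasing")
  expect_error(validate_flow_trace(tr[tr$segment == "animal", ]),
               "no baseline")
  bad2 <- tr
  bad2$segment[1] <- "warmup"
  expect_error(validate_flow_trace(bad2), "unknown segment")
})
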