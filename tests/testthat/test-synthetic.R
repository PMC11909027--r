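cfg0 <- sim_config(seed = 17)

test_that("every generator is deterministic under a fixed master seed", {
  expect_identical(synth_morphometrics(cfg0), synth_morphometrics(cfg0))
  expect_identical(synth_flow_trace(cfg0, 5e-6), synth_flow_trace(cfg0, 5e-6))
  expect_identical(synth_tb_series(cfg0), synth_tb_series(cfg0))
  expect_identical(synth_occupancy(cfg0, "27H/32D"),
                   synth_occupancy(cfg0, "27H/32D"))
})

test_that("adding animals does not perturb existing draws", {
  small <- synth_morphometrics(cfg0)
  cfg_big <- sim_config(seed = 17)
  cfg_big$species$ewl_n_dry <- cfg_big$species$ewl_n_dry + 5L
  big <- synth_morphometrics(cfg_big)
  merged <- merge(small, big, by = "animal_id")
  expect_equal(nrow(merged), nrow(small))
  expect_equal(merged$mass_g.x, merged$mass_g.y)
  expect_equal(merged$svl_mm.x, merged$svl_mm.y)
})

test_that("synthetic masses follow the configured species distributions", {
  cfg <- sim_config(seed = 31)
  cfg$species$ewl_n_dry <- rep(150L, 3)
  cfg$species$ewl_n_wet <- rep(2L, 3)
  m <- synth_morphometrics(cfg)
  m <- m[m$season == "dry", ]
  means <- tapply(m$mass_g, m$species, mean)
  for (i in seq_len(3)) {
    sp <- cfg$species$species[i]
    se <- cfg$species$mass_sd_dry[i] / sqrt(150)
    expect_lt(abs(means[[sp]] - cfg$species$mass_mean_dry[i]), 3 * se)
  }
  # configured size ordering: house gecko > Bynoe's > zig-zag
  expect_gt(means[["Hemidactylus frenatus"]], means[["Heteronotia binoei"]])
  expect_gt(means[["Heteronotia binoei"]], means[["Amalosia rhombifer"]])
  # gravid flags only on females
  full <- synth_morphometrics(cfg0)
  expect_true(all(full$sex[full$gravid] == "F"))
})

test_that("flow traces carry their configured water flux", {
  # zero flux: animal plateau sits at baseline humidity
  cfg_q <- sim_config(seed = 7, movement_artifact_rate = 0,
                      trace_noise_sd = 0.05)
  tr0 <- synth_flow_trace(cfg_q, 0)
  an <- tr0$rh_pct[tr0$segment == "animal"]
  bl <- tr0$rh_pct[tr0$segment == "baseline_pre"]
  expect_lt(abs(mean(an) - mean(bl)), 0.05)

  # known flux recovered by the analysis chain at low noise
  cfg_lo <- sim_config(seed = 7, trace_noise_sd = 0.02)
  for (mw in c(2e-6, 6e-6, 1.2e-5)) {
    tr <- synth_flow_trace(cfg_lo, mw)
    truth <- attr(tr, "truth")
    expect_equal(truth$mw_g_s, mw)
    got <- compute_ewl(tr, list(flow_rate_l_min = cfg_lo$flow_rate_l_min))
    expect_equal(got$mw_g_s, mw, tolerance = 0.02)
    # the detected window sits on the plateau, never on an excursion:
    # its mean humidity cannot exceed the quiet stretch's
    quiet <- tr$segment == "animal" &
      tr$time_s >= truth$rest_start_s & tr$time_s <= truth$rest_end_s
    expect_lte(detect_resting_window(tr)$mean_rh_pct,
               mean(tr$rh_pct[quiet]) + 0.05)
  }
})

test_that("body-temperature series recover the configured preferences", {
  # near-zero spread pins the preferred temperature to the configured mean
  cfg_t <- sim_config(seed = 9)
  cfg_t$species$tpref_sd <- rep(1e-6, 3)
  tb <- synth_tb_series(cfg_t)
  tp <- reduce_tpref(tb)$summary
  for (i in seq_len(3)) {
    sp <- cfg_t$species$species[i]
    dry <- tp$tpref_c[tp$species == sp & tp$season == "dry"]
    expect_equal(mean(dry), cfg_t$species$tpref_mean_dry[i], tolerance = 1e-4)
  }

  # the configured seasonal shift of the zig-zag gecko is recovered at the
  # study sample sizes (dry n = 9, wet n = 16)
  tb2 <- synth_tb_series(cfg0)
  tp2 <- reduce_tpref(tb2)$summary
  ar <- tp2[tp2$species == "Amalosia rhombifer", ]
  shift <- mean(ar$tpref_c[ar$season == "dry"]) -
    mean(ar$tpref_c[ar$season == "wet"])
  cfg_shift <- cfg0$species$tpref_mean_dry[1] - cfg0$species$tpref_mean_wet[1]
  se <- cfg0$species$tpref_sd[1] * sqrt(1 / 9 + 1 / 16)
  expect_lt(abs(shift - cfg_shift), 3 * se)
  expect_true(all(tb2$tb_c >= 20 & tb2$tb_c <= 40))
})

test_that("occupancy chains hit their stationary distribution", {
  # no open time when the stationary mass sits entirely on the refuges
  cfg_r <- sim_config(seed = 13)
  cfg_r$refuge_stationary[["32H/32D"]] <-
    c(humid = 0.7, dry = 0.3, open = 0)
  log0 <- synth_occupancy(cfg_r, "32H/32D")
  expect_equal(summarize_occupancy(log0)$p_refuge, 1)

  # long-run frequencies within 3 SE of the stationary probabilities,
  # with the SE inflated for the chain's autocorrelation (stickiness s
  # gives an effective variance factor (1 + s) / (1 - s))
  log <- synth_occupancy(cfg0, "22H/32D")
  truth <- attr(log, "truth")$stationary
  n <- nrow(log)
  infl <- (1 + cfg0$refuge_stickiness) / (1 - cfg0$refuge_stickiness)
  for (stt in names(truth)) {
    p_hat <- mean(log$state == stt)
    se <- sqrt(truth[[stt]] * (1 - truth[[stt]]) / n * infl)
    expect_lt(abs(p_hat - truth[[stt]]), 3 * se,
              label = paste("stationary recovery for state", stt))
  }
  expect_error(synth_occupancy(cfg0, "30H/32D"), "unknown treatment")
})

test_that("the assembled study is internally consistent", {
  cfg <- sim_config(seed = 29, refuge_n_frames = 240L)
  cfg$species$ewl_n_dry <- c(2L, 2L, 2L)
  cfg$species$ewl_n_wet <- c(2L, 2L, 2L)
  cfg$species$refuge_n <- c(2L, 1L, 1L)
  st <- synth_study(cfg)
  expect_setequal(st$ewl_meta$animal_id, names(st$traces))
  expect_setequal(st$ewl_meta$animal_id, st$ground_truth$animal_id)
  expect_true(all(st$ewl_meta$skin_temp_c >= 15 &
                    st$ewl_meta$skin_temp_c <= 45))
  # ground-truth resistance is consistent with its own components
  gt <- st$ground_truth
  r_check <- (saturation_vapour_density(gt$skin_temp_c) - gt$true_vd_a_g_cm3) /
    gt$true_ec_g_cm2_s
  expect_equal(gt$true_resistance_s_cm, r_check, tolerance = 1e-8)
  # every refuge animal appears in all three treatments
  tab <- table(st$occupancy$animal_id, st$occupancy$treatment)
  expect_true(all(tab == 240L))
})
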