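# Independent oracles, deliberately written without reusing package
# internals, so implementation and check stay decoupled.

# Arden Buck (1996) saturation vapour pressure, kPa, coded from the
# published constants.
oracle_buck96 <- function(t) {
  0.61121 * exp((18.678 - t / 234.5) * (t / (257.14 + t)))
}

# Ideal-gas vapour density, g cm^-3, from first principles.
oracle_vd <- function(t, rh) {
  (oracle_buck96(t) * rh / 100 * 1000) / (461.5 * (t + 273.15)) * 1000 / 1e6
}

# Exhaustive resting-window scan: evaluate EVERY candidate rest window and
# EVERY candidate read window by direct subsetting (sd()/mean() on explicit
# index sets), then qualify each read window against each rest window with
# an outer comparison. Deliberately naive; no rolling-sum machinery.
oracle_resting_window <- function(trace, rest_min_s = 300,
                                  read_window_s = 120, flat_sd_max = 0.5) {
  an <- trace[trace$segment == "animal", ]
  t <- an$time_s
  rh <- an$rh_pct
  t_end <- t[length(t)]
  flat <- sapply(seq_along(t), function(i) {
    if (t[i] + rest_min_s > t_end + 1e-9) return(FALSE)
    sd(rh[t >= t[i] - 1e-9 & t <= t[i] + rest_min_s + 1e-9]) <= flat_sd_max
  })
  read_ok <- t + read_window_s <= t_end + 1e-9
  means <- sapply(seq_along(t), function(j) {
    if (!read_ok[j]) return(Inf)
    mean(rh[t >= t[j] - 1e-9 & t <= t[j] + read_window_s + 1e-9])
  })
  # rest window i contains read window j
  contains <- outer(t, t, function(ti, tj)
    ti <= tj + 1e-9 & ti + rest_min_s >= tj + read_window_s - 1e-9)
  qualified <- read_ok & (colSums(contains & flat) > 0)
  if (!any(qualified)) return(NULL)
  means[!qualified] <- Inf
  j <- which.min(means)
  list(start_s = t[j], mean = means[j])
}

# Minimal hand-built trace: flat baselines plus an animal segment given as
# an RH vector sampled every `dt` seconds.
make_trace <- function(animal_rh, dt = 5, baseline_rh = 2,
                       baseline_s = 120, temp_c = 30) {
  nb <- baseline_s / dt
  na <- length(animal_rh)
  time_s <- seq(0, by = dt, length.out = nb + na + nb)
  data.frame(
    time_s = time_s,
    rh_pct = c(rep(baseline_rh, nb), animal_rh, rep(baseline_rh, nb)),
    temp_c = temp_c,
    segment = rep(c("baseline_pre", "animal", "baseline_post"),
                  c(nb, na, nb))
  )
}
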