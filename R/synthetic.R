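# Seeded synthetic-data generators. They emulate the structure of a
# two-season, three-species gecko ecophysiology study -- seasonal EWL
# multiplier, seasonal resistance ratio, species-level mass distributions,
# flow-through humidity traces with rest plateaus and movement artefacts,
# 12-reading gradient body-temperature series, and 10-s-interval
# three-state refuge logs -- with every ground-truth quantity recorded, so
# the analysis chain can be validated end to end.

# Deterministic sub-seed per generator stream: a fixed master seed plus a
# string key always yields the same stream, and streams are independent of
# how many other streams were drawn before them.
.sub_seed <- function(seed, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147480009
  as.integer((h + (seed %% 1000003) * 1013) %% 2147483629) + 1L
}

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.species_abbrev <- c("Amalosia rhombifer" = "Ar",
                     "Heteronotia binoei" = "Hb",
                     "Hemidactylus frenatus" = "Hf")

# Fabricated allometric coefficients linking mass to linear measurements.
# Only their positivity matters to the analysis chain; they produce
# gecko-plausible shapes (SVL ~ 60 mm at 1.5 g).
.allometry <- list(svl_per_g13_mm = 52, torso_w = 0.14, tail_l = 0.90,
                   tail_w = 0.07, leg_l = 0.30, leg_w = 0.045,
                   noise_sd = 0.04)

#' Configuration for a synthetic gecko ecophysiology study
#'
#' Bundles every tunable of the synthetic-data generators. The defaults are
#' the study conditions: per-species, per-season sample sizes and body-mass
#' distributions of the three species; a dry-season EWL multiplier of 0.655
#' (dry rates average 65.5% of wet rates); a dry/wet total-resistance ratio
#' of 1.54; a 2.7 degC lower wet-season thermal preference for
#' *A. rhombifer*; 12 hourly gradient readings per animal; 20-h refuge
#' trials scored every 10 s; and a 0.2 L min^-1 flow-through system at a
#' nominal 30 degC with fully dried inflow air.
#'
#' @param seed Master RNG seed. Every generator stream is derived from it
#'   deterministically, so a fixed seed gives byte-identical outputs and
#'   adding animals does not perturb existing draws.
#' @param ... Named overrides of any default listed below (unknown names
#'   are an error).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, trace_noise_sd = 0.05)
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    species = data.frame(
      species = names(.species_abbrev),
      ewl_n_dry = c(9L, 11L, 9L),
      ewl_n_wet = c(16L, 6L, 10L),
      mass_mean_dry = c(1.52, 2.23, 3.46),
      mass_sd_dry = c(0.212, 0.568, 0.948),
      mass_mean_wet = c(1.50, 1.96, 3.53),
      mass_sd_wet = c(0.261, 0.482, 0.929),
      tpref_n_dry = c(9L, 10L, 10L),
      tpref_n_wet = c(16L, 6L, 9L),
      tpref_mean_dry = c(30.0, 30.8, 31.5),
      tpref_mean_wet = c(27.3, 30.3, 31.0),
      tpref_sd = c(1.2, 1.2, 1.2),
      refuge_n = c(9L, 7L, 9L),
      stringsAsFactors = FALSE
    ),
    season_ewl_ratio = 0.655,        # dry-season multiplier on wet EWL
    resistance_ratio_dry_wet = 1.54, # dry/wet total resistance
    resistance_wet_median_s_cm = 150,
    resistance_log_sd = 0.20,
    mw_scale_g_s_per_g067 = 4e-6,    # wet-season M_w per (species mass)^0.67
    mw_log_sd = 0.25,
    gravid_fraction = 0.25,          # of females
    # flow-through trace generation
    flow_rate_l_min = 0.2,
    chamber_temp_c = 30,
    baseline_rh_pct = 2,
    trace_noise_sd = 0.2,            # %RH
    movement_artifact_rate = 1 / 240, # events per second of animal segment
    artifact_amp_rh = 4,             # mean excursion height, %RH
    artifact_decay_s = 30,
    sample_interval_s = 5,
    baseline_s = 300,
    animal_s = 1800,
    rest_quiet_s = c(900, 1500),     # artefact-free stretch (animal segment)
    # thermal gradient
    tb_n_readings = 12L,
    # refuge trials
    refuge_stationary = list(
      "22H/32D" = c(humid = 0.25, dry = 0.55, open = 0.20),
      "27H/32D" = c(humid = 0.40, dry = 0.40, open = 0.20),
      "32H/32D" = c(humid = 0.60, dry = 0.25, open = 0.15)
    ),
    refuge_stickiness = 0.98,        # P(stay) per 10-s frame
    refuge_n_frames = 7200L,         # 20 h at 10 s
    frame_interval_s = 10
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown sim_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$season_ewl_ratio > 0, cfg$resistance_ratio_dry_wet > 0,
            all(vapply(cfg$refuge_stationary,
                       function(p) all(p >= 0) && abs(sum(p) - 1) < 1e-8,
                       logical(1))))
  class(cfg) <- c("sim_config", "list")
  cfg
}

.truncnorm1 <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}

#' Generate a synthetic morphometrics table
#'
#' Masses are drawn from the configured species x season normal
#' distributions (truncated above zero); linear measurements follow
#' fabricated positive allometric coefficients (SVL proportional to
#' mass^(1/3) with lognormal measurement noise); sexes are balanced and a
#' configurable fraction of females is flagged gravid.
#'
#' @param cfg A [sim_config()].
#' @param experiment Which experiment's sample sizes to use: `"ewl"`,
#'   `"tpref"` (both seasons) or `"refuge"` (single season, labelled wet).
#' @return Data frame, one row per animal: `animal_id`, `species`, `sex`,
#'   `season`, `gravid`, `mass_g`, `svl_mm`, `torso_l_mm`, `torso_w_mm`,
#'   `tail_l_mm`, `tail_w_mm`, `leg1_l_mm`, ..., `leg4_w_mm`.
#' @export
synth_morphometrics <- function(cfg, experiment = c("ewl", "tpref",
                                                    "refuge")) {
  experiment <- match.arg(experiment)
  sp <- cfg$species
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    seasons <- if (experiment == "refuge") "wet" else c("dry", "wet")
    for (season in seasons) {
      n <- switch(experiment,
                  ewl = if (season == "dry") sp$ewl_n_dry[i] else sp$ewl_n_wet[i],
                  tpref = if (season == "dry") sp$tpref_n_dry[i] else sp$tpref_n_wet[i],
                  refuge = sp$refuge_n[i])
      m_mean <- if (season == "dry") sp$mass_mean_dry[i] else sp$mass_mean_wet[i]
      m_sd <- if (season == "dry") sp$mass_sd_dry[i] else sp$mass_sd_wet[i]
      for (k in seq_len(n)) {
        id <- sprintf("%s_%s_%s_%02d", .species_abbrev[[sp$species[i]]],
                      experiment, season, k)
        rows[[id]] <- .with_seed(
          .sub_seed(cfg$seed, "morpho", experiment, sp$species[i], season, k), {
            mass <- .truncnorm1(m_mean, m_sd, lower = 0.2)
            sex <- if (stats::runif(1) < 0.5) "F" else "M"
            gravid <- sex == "F" && stats::runif(1) < cfg$gravid_fraction
            al <- .allometry
            jit <- function() exp(stats::rnorm(1, 0, al$noise_sd))
            svl <- al$svl_per_g13_mm * mass^(1 / 3) * jit()
            data.frame(
              animal_id = id, species = sp$species[i], sex = sex,
              season = season, gravid = gravid, mass_g = mass, svl_mm = svl,
              torso_l_mm = svl, torso_w_mm = al$torso_w * svl * jit(),
              tail_l_mm = al$tail_l * svl * jit(),
              tail_w_mm = al$tail_w * svl * jit(),
              leg1_l_mm = al$leg_l * svl * jit(),
              leg1_w_mm = al$leg_w * svl * jit(),
              leg2_l_mm = al$leg_l * svl * jit(),
              leg2_w_mm = al$leg_w * svl * jit(),
              leg3_l_mm = al$leg_l * svl * jit(),
              leg3_w_mm = al$leg_w * svl * jit(),
              leg4_l_mm = al$leg_l * svl * jit(),
              leg4_w_mm = al$leg_w * svl * jit(),
              stringsAsFactors = FALSE)
          })
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic flow-through humidity trace
#'
#' Builds the downstream probe signal of an open-flow trial with known
#' water flux: dry-air baselines before and after, an animal segment whose
#' rest plateau sits at \eqn{VD_a = VD_i + M_w / V_e}, Gaussian probe noise,
#' and Poisson-timed movement excursions (exponentially decaying humidity
#' spikes). A configurable stretch of the animal segment
#' (`cfg$rest_quiet_s`) is kept free of artefacts: the animal eventually
#' settles, which is what makes a resting read possible.
#'
#' @param cfg A [sim_config()].
#' @param true_mw_g_s True water mass flow, g s^-1 (>= 0).
#' @param flow_rate_l_min Pump flow; defaults to the configured value.
#' @param chamber_temp_c Chamber air temperature; defaults to configured.
#' @param seed Stream seed; defaults to a stream derived from
#'   `cfg$seed` and the arguments.
#' @return A flow-trace data frame (`time_s`, `rh_pct`, `temp_c`,
#'   `segment`) with a `"truth"` attribute: `mw_g_s`, `vd_i_g_cm3`,
#'   `vd_a_g_cm3`, `rest_start_s`, `rest_end_s`.
#' @export
synth_flow_trace <- function(cfg, true_mw_g_s,
                             flow_rate_l_min = cfg$flow_rate_l_min,
                             chamber_temp_c = cfg$chamber_temp_c,
                             seed = NULL) {
  stopifnot(true_mw_g_s >= 0)
  if (is.null(seed)) {
    seed <- .sub_seed(cfg$seed, "trace", signif(true_mw_g_s, 8))
  }
  dt <- cfg$sample_interval_s
  t_pre <- seq(0, cfg$baseline_s - dt, by = dt)
  t_an <- seq(cfg$baseline_s, cfg$baseline_s + cfg$animal_s - dt, by = dt)
  t_post <- seq(cfg$baseline_s + cfg$animal_s,
                2 * cfg$baseline_s + cfg$animal_s - dt, by = dt)
  ve <- flow_l_min_to_cm3_s(flow_rate_l_min)
  svd_ch <- saturation_vapour_density(chamber_temp_c)
  vd_i <- vapour_density(chamber_temp_c, cfg$baseline_rh_pct)
  vd_a <- vd_i + true_mw_g_s / ve
  rh_a <- min(99.5, vd_a / svd_ch * 100)

  .with_seed(seed, {
    n_an <- length(t_an)
    rh_animal <- rep(rh_a, n_an)
    # movement excursions: Poisson-timed, exponential height, decaying tails;
    # none allowed to touch the quiet rest stretch
    q <- cfg$rest_quiet_s
    n_ev <- stats::rpois(1, cfg$movement_artifact_rate * cfg$animal_s)
    if (n_ev > 0) {
      ev <- stats::runif(n_ev, 0, cfg$animal_s)
      guard <- 6 * cfg$artifact_decay_s
      ev <- ev[ev < q[1] - guard | ev > q[2]]
      for (e in ev) {
        amp <- stats::rexp(1, 1 / cfg$artifact_amp_rh) + 1
        rel <- (t_an - cfg$baseline_s) - e
        rh_animal <- rh_animal +
          amp * exp(-pmax(rel, 0) / cfg$artifact_decay_s) * (rel >= 0)
      }
    }
    time_s <- c(t_pre, t_an, t_post)
    rh <- c(rep(cfg$baseline_rh_pct, length(t_pre)), rh_animal,
            rep(cfg$baseline_rh_pct, length(t_post))) +
      stats::rnorm(length(time_s), 0, cfg$trace_noise_sd)
    rh <- pmin(100, pmax(0, rh))
    trace <- data.frame(
      time_s = time_s,
      rh_pct = rh,
      temp_c = chamber_temp_c + stats::rnorm(length(time_s), 0, 0.05),
      segment = rep(c("baseline_pre", "animal", "baseline_post"),
                    c(length(t_pre), n_an, length(t_post))),
      stringsAsFactors = FALSE
    )
    attr(trace, "truth") <- list(
      mw_g_s = true_mw_g_s, vd_i_g_cm3 = vd_i, vd_a_g_cm3 = vd_a,
      rest_start_s = cfg$baseline_s + q[1], rest_end_s = cfg$baseline_s + q[2])
    trace
  })
}

#' Generate synthetic gradient body-temperature series
#'
#' For each animal of the thermal-preference sample, `tb_n_readings`
#' (nominally 12, hourly) dorsal temperatures drawn around the configured
#' species x season preferred temperature, truncated to the gradient range
#' \[20, 40\] degC.
#'
#' @param cfg A [sim_config()].
#' @return Long data frame: `animal_id`, `species`, `sex`, `season`,
#'   `reading_idx`, `tb_c`.
#' @export
synth_tb_series <- function(cfg) {
  sp <- cfg$species
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    for (season in c("dry", "wet")) {
      n <- if (season == "dry") sp$tpref_n_dry[i] else sp$tpref_n_wet[i]
      mu <- if (season == "dry") sp$tpref_mean_dry[i] else sp$tpref_mean_wet[i]
      for (k in seq_len(n)) {
        id <- sprintf("%s_tpref_%s_%02d", .species_abbrev[[sp$species[i]]],
                      season, k)
        rows[[id]] <- .with_seed(
          .sub_seed(cfg$seed, "tb", sp$species[i], season, k), {
            sex <- if (stats::runif(1) < 0.5) "F" else "M"
            tb <- stats::rnorm(cfg$tb_n_readings, mu, sp$tpref_sd[i])
            while (any(tb < 20 | tb > 40)) {
              out <- tb < 20 | tb > 40
              tb[out] <- stats::rnorm(sum(out), mu, sp$tpref_sd[i])
            }
            data.frame(animal_id = id, species = sp$species[i], sex = sex,
                       season = season,
                       reading_idx = seq_len(cfg$tb_n_readings), tb_c = tb,
                       stringsAsFactors = FALSE)
          })
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic refuge-occupancy log
#'
#' A sticky three-state Markov chain over {humid, dry, open}: at each
#' 10-s frame the animal stays put with probability
#' `cfg$refuge_stickiness`, otherwise it redraws its state from the
#' treatment's stationary distribution. By construction the chain's
#' stationary distribution equals the configured state probabilities, so
#' long-run occupancy frequencies are known exactly.
#'
#' @param cfg A [sim_config()].
#' @param treatment One of `"22H/32D"`, `"27H/32D"`, `"32H/32D"`.
#' @param n_frames Number of scored frames (default `cfg$refuge_n_frames`).
#' @param seed Stream seed; defaults to a stream derived from `cfg$seed`
#'   and the treatment.
#' @return Data frame `time_s`, `state` with a `"truth"` attribute holding
#'   the stationary probabilities.
#' @export
synth_occupancy <- function(cfg, treatment, n_frames = cfg$refuge_n_frames,
                            seed = NULL) {
  if (!treatment %in% names(cfg$refuge_stationary)) {
    stop("unknown treatment: ", treatment, call. = FALSE)
  }
  if (is.null(seed)) seed <- .sub_seed(cfg$seed, "occupancy", treatment)
  pi0 <- cfg$refuge_stationary[[treatment]]
  states <- names(pi0)
  .with_seed(seed, {
    redraw <- sample.int(length(pi0), n_frames, replace = TRUE, prob = pi0)
    stay <- stats::runif(n_frames) < cfg$refuge_stickiness
    stay[1L] <- FALSE
    grp <- cumsum(!stay)
    state <- states[redraw[!stay][grp]]
    log <- data.frame(time_s = (seq_len(n_frames) - 1L) * cfg$frame_interval_s,
                      state = state, stringsAsFactors = FALSE)
    attr(log, "truth") <- list(stationary = pi0, treatment = treatment)
    log
  })
}

# Invert saturation vapour density: the skin temperature whose saturated
# skin surface has the given vapour density.
.skin_temp_for_vd <- function(vd_g_cm3, formulation = "buck1996") {
  stats::uniroot(function(t) saturation_vapour_density(t, formulation) - vd_g_cm3,
                 interval = c(15, 45), tol = 1e-10)$root
}

#' Generate a complete synthetic study with ground truth
#'
#' Draws the full input suite the pipeline consumes: EWL morphometrics and
#' one flow-through trace per animal for both seasons of all three species,
#' the thermal-gradient series, and refuge logs for every animal x
#' treatment. True per-animal water flux is the species-level scale
#' (set by the species' grand-mean mass) times the seasonal multiplier
#' (`season_ewl_ratio` in the dry season) times lognormal individual
#' variation, so the geometric-mean dry/wet EWL ratio equals the configured
#' value in expectation. True total resistance is drawn around the
#' configured wet-season median (times `resistance_ratio_dry_wet` in the
#' dry season) and realised exactly by solving for the skin temperature
#' whose saturation vapour density gives that resistance; skin temperatures
#' are clamped to \[16, 44\] degC and the recorded ground-truth resistance
#' is recomputed from the realised skin temperature.
#'
#' @param cfg A [sim_config()].
#' @return List with `morpho`, `ewl_meta` (per-trial metadata incl. skin
#'   temperature and surface area), `traces` (named list of flow traces),
#'   `tb` (long body-temperature table), `occupancy` (frame log with
#'   `animal_id`, `treatment`, `time_s`, `state`), `ground_truth` (per
#'   trial: true M_w, E_c, resistance, vapour densities), and `config`.
#' @export
synth_study <- function(cfg) {
  morpho <- synth_morphometrics(cfg, "ewl")
  sa <- total_surface_area(morpho)
  ve <- flow_l_min_to_cm3_s(cfg$flow_rate_l_min)
  vd_i <- vapour_density(cfg$chamber_temp_c, cfg$baseline_rh_pct)
  grand_mass <- vapply(seq_len(nrow(cfg$species)), function(i) {
    mean(c(cfg$species$mass_mean_dry[i], cfg$species$mass_mean_wet[i]))
  }, numeric(1))
  names(grand_mass) <- cfg$species$species

  traces <- list()
  meta_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(morpho))) {
    id <- morpho$animal_id[i]
    season_mult <- if (morpho$season[i] == "dry") cfg$season_ewl_ratio else 1
    res_mult <- if (morpho$season[i] == "dry") cfg$resistance_ratio_dry_wet else 1
    draws <- .with_seed(.sub_seed(cfg$seed, "ewl_truth", id), {
      c(mw = stats::rlnorm(1, log(cfg$mw_scale_g_s_per_g067 *
                                    grand_mass[[morpho$species[i]]]^0.67 *
                                    season_mult), cfg$mw_log_sd),
        res = stats::rlnorm(1, log(cfg$resistance_wet_median_s_cm * res_mult),
                            cfg$resistance_log_sd))
    })
    mw <- draws[["mw"]]
    ec <- mw / sa[i]
    vd_a <- vd_i + mw / ve
    vd_s_target <- min(saturation_vapour_density(44),
                       max(saturation_vapour_density(16),
                           draws[["res"]] * ec + vd_a))
    skin <- .skin_temp_for_vd(vd_s_target)
    res_true <- (saturation_vapour_density(skin) - vd_a) / ec
    traces[[id]] <- synth_flow_trace(cfg, mw,
                                     seed = .sub_seed(cfg$seed, "trace", id))
    meta_rows[[id]] <- data.frame(
      animal_id = id, species = morpho$species[i], season = morpho$season[i],
      sex = morpho$sex[i], mass_g = morpho$mass_g[i],
      flow_rate_l_min = cfg$flow_rate_l_min,
      chamber_temp_nominal_c = cfg$chamber_temp_c,
      skin_temp_c = skin, surface_area_cm2 = sa[i],
      stringsAsFactors = FALSE)
    truth_rows[[id]] <- data.frame(
      animal_id = id, species = morpho$species[i], season = morpho$season[i],
      true_mw_g_s = mw, true_ec_g_cm2_s = ec, true_resistance_s_cm = res_true,
      true_vd_a_g_cm3 = vd_a, true_vd_i_g_cm3 = vd_i,
      surface_area_cm2 = sa[i], skin_temp_c = skin,
      stringsAsFactors = FALSE)
  }

  refuge_morpho <- synth_morphometrics(cfg, "refuge")
  occ_rows <- list()
  for (i in seq_len(nrow(refuge_morpho))) {
    id <- refuge_morpho$animal_id[i]
    for (tr in names(cfg$refuge_stationary)) {
      log <- synth_occupancy(cfg, tr,
                             seed = .sub_seed(cfg$seed, "occupancy", id, tr))
      occ_rows[[paste(id, tr)]] <- data.frame(
        animal_id = id, species = refuge_morpho$species[i], treatment = tr,
        log, stringsAsFactors = FALSE)
    }
  }
  occupancy <- do.call(rbind, occ_rows)
  rownames(occupancy) <- NULL

  ewl_meta <- do.call(rbind, meta_rows)
  ground_truth <- do.call(rbind, truth_rows)
  rownames(ewl_meta) <- rownames(ground_truth) <- NULL
  list(morpho = morpho, ewl_meta = ewl_meta, traces = traces,
       tb = synth_tb_series(cfg), occupancy = occupancy,
       ground_truth = ground_truth, config = cfg)
}
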