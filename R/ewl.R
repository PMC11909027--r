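# Reduction of open-flow hygrometry traces to resting evaporative water loss
# (EWL), area-specific EWL and total resistance to water loss.
#
# A trial trace is a data frame with columns time_s (strictly increasing),
# rh_pct, temp_c and segment ("baseline_pre", "animal", "baseline_post"):
# dried air is drawn through the animal chamber at a known flow rate and the
# downstream humidity rise carries the animal's water flux.

.segment_levels <- c("baseline_pre", "animal", "baseline_post")

#' Validate a flow-through hygrometry trace
#'
#' @param trace Data frame with columns `time_s`, `rh_pct`, `temp_c`,
#'   `segment`.
#' @param require_baselines Require at least one baseline segment (default
#'   TRUE).
#' @return The trace, invisibly, with `segment` as character.
#' @export
validate_flow_trace <- function(trace, require_baselines = TRUE) {
  need <- c("time_s", "rh_pct", "temp_c", "segment")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trace) < 2L) stop("trace has fewer than 2 rows", call. = FALSE)
  if (any(diff(trace$time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(trace$rh_pct < 0 | trace$rh_pct > 100)) {
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  }
  seg <- as.character(trace$segment)
  bad <- setdiff(unique(seg), .segment_levels)
  if (length(bad)) {
    stop("unknown segment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"animal" %in% seg) stop("trace has no 'animal' segment", call. = FALSE)
  if (require_baselines && !any(seg != "animal")) {
    stop("trace has no baseline segment", call. = FALSE)
  }
  trace$segment <- seg
  invisible(trace)
}

#' Convert a pump flow rate from L min^-1 to cm^3 s^-1
#'
#' @param flow_l_min Flow rate, L min^-1.
#' @return Flow rate, cm^3 s^-1 (`flow_l_min * 1000 / 60`).
#' @examples
#' flow_l_min_to_cm3_s(0.2)  # 3.333 cm^3 s^-1
#' @export
flow_l_min_to_cm3_s <- function(flow_l_min) {
  stopifnot(is.numeric(flow_l_min))
  flow_l_min * 1000 / 60
}

# Rolling window bookkeeping over an irregular time grid: for each start
# index, the last index whose time lies within `width_s` (inclusive) and the
# window mean / sd of `x`, computed with cumulative sums.
.time_windows <- function(time_s, x, width_s) {
  n <- length(time_s)
  end <- findInterval(time_s + width_s + 1e-9, time_s)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  cnt <- end - seq_len(n) + 1L
  s1 <- cs[end] - c(0, cs)[seq_len(n)]
  s2 <- cs2[end] - c(0, cs2)[seq_len(n)]
  mu <- s1 / cnt
  var <- pmax(0, (s2 - s1^2 / cnt) / pmax(1L, cnt - 1L))
  # a window is complete if it spans the full width
  complete <- (time_s + width_s) <= time_s[n] + 1e-9
  list(end = end, n = cnt, mean = mu, sd = sqrt(var), complete = complete)
}

#' Detect the resting measurement window in a flow-through trace
#'
#' Movement inflates water loss and produces an irregular humidity trace; a
#' flat-line trace indicates a resting animal. The resting read is taken as
#' the `read_window_s` (default 2 min) sub-window with the lowest mean
#' humidity, constrained to lie inside a rest period of at least
#' `rest_min_s` (default 5 min) over which the humidity trace is flat
#' (rolling standard deviation at most `flat_sd_max` %RH). Ties in mean
#' humidity are broken in favour of the earliest window, so the result is
#' deterministic.
#'
#' @param trace A flow trace (see [validate_flow_trace()]); only the
#'   `"animal"` segment is scanned.
#' @param rest_min_s Minimum duration of a qualifying rest period, s.
#' @param read_window_s Width of the reading window, s.
#' @param flat_sd_max Flatness criterion: maximum standard deviation of
#'   relative humidity over a rest period, %RH.
#' @return A list with `start_s`, `end_s` (the reading window bounds) and
#'   `mean_rh_pct` (its mean humidity).
#' @export
detect_resting_window <- function(trace, rest_min_s = 300,
                                  read_window_s = 120, flat_sd_max = 0.5) {
  trace <- validate_flow_trace(trace, require_baselines = FALSE)
  an <- trace[trace$segment == "animal", , drop = FALSE]
  t <- an$time_s
  if (length(t) < 3L || (t[length(t)] - t[1L]) < rest_min_s) {
    stop("animal segment shorter than rest_min_s; no rest period possible",
         call. = FALSE)
  }
  rest <- .time_windows(t, an$rh_pct, rest_min_s)
  rest_ok <- rest$complete & rest$sd <= flat_sd_max
  if (!any(rest_ok)) {
    stop("no rest period detected (no flat ", rest_min_s,
         " s stretch with sd <= ", flat_sd_max, " %RH); re-run the trial",
         call. = FALSE)
  }
  read <- .time_windows(t, an$rh_pct, read_window_s)
  # a reading window qualifies if some flat rest period contains it entirely:
  # a rest start at time u covers reads starting in [u, u + rest - read]
  n <- length(t)
  csok <- cumsum(rest_ok)
  lo <- findInterval(t - (rest_min_s - read_window_s) - 1e-9, t) + 1L
  hi <- findInterval(t + 1e-9, t)
  any_rest <- (csok[hi] - c(0, csok)[lo]) > 0
  read_ok <- read$complete & any_rest
  if (!any(read_ok)) {
    stop("no reading window fits inside a detected rest period", call. = FALSE)
  }
  means <- ifelse(read_ok, read$mean, Inf)
  j <- which.min(means)  # which.min takes the first minimum: earliest wins
  list(start_s = t[j], end_s = t[j] + read_window_s,
       mean_rh_pct = read$mean[j])
}

#' Compute resting evaporative water loss from a trial trace
#'
#' Implements the open-flow mass balance \eqn{M_w = V_e (VD_a - VD_i)}:
#' the baseline vapour density \eqn{VD_i} is the mean over the pre- and
#' post-trial baseline segments, \eqn{VD_a} is the vapour density in the
#' detected resting window of the animal segment, and \eqn{V_e} is the
#' experimental flow rate converted to cm^3 s^-1. Vapour densities are
#' computed from each probe reading's own measured air temperature.
#'
#' If the pre and post baselines disagree by more than
#' `baseline_drift_tol_g_cm3` the trial is drift-corrected: \eqn{VD_i} is
#' interpolated linearly in time between the two baseline means, evaluated
#' at the midpoint of the resting window (with a warning). A trial whose
#' chamber vapour density falls below baseline by more than the same
#' tolerance is flagged invalid (`valid = FALSE`).
#'
#' @param trace A flow trace (see [validate_flow_trace()]).
#' @param meta List or one-row data frame of trial metadata. Required:
#'   `flow_rate_l_min`. Optional: `skin_temp_c` (degC, in \[15, 45\]) and
#'   `surface_area_cm2`, which enable the area-specific rate and total
#'   resistance; `animal_id`, `species`, `season`, `sex`, `mass_g` are
#'   carried through to the result.
#' @inheritParams detect_resting_window
#' @param baseline_drift_tol_g_cm3 Tolerated difference between pre and post
#'   baseline vapour densities, g cm^-3, before drift correction kicks in.
#' @param formulation Saturation vapour pressure formulation, see
#'   [saturation_vapour_pressure()].
#' @return A one-row data frame (class `ewl_result`) with the identifiers,
#'   `vd_baseline_g_cm3`, `vd_animal_g_cm3`, `mw_g_s`, `mw_g_h`,
#'   `ec_g_cm2_s`, `resistance_s_cm` (NA when surface area or skin
#'   temperature is not supplied), `rest_start_s`, `rest_end_s`, `valid`.
#' @export
compute_ewl <- function(trace, meta, rest_min_s = 300, read_window_s = 120,
                        flat_sd_max = 0.5, baseline_drift_tol_g_cm3 = 2e-7,
                        formulation = "buck1996") {
  trace <- validate_flow_trace(trace)
  meta <- as.list(meta)
  if (is.null(meta$flow_rate_l_min) || !is.numeric(meta$flow_rate_l_min) ||
      meta$flow_rate_l_min <= 0) {
    stop("meta$flow_rate_l_min must be a positive number", call. = FALSE)
  }
  if (!is.null(meta$skin_temp_c) && !is.na(meta$skin_temp_c) &&
      (meta$skin_temp_c < 15 || meta$skin_temp_c > 45)) {
    stop("meta$skin_temp_c outside plausible range [15, 45] degC",
         call. = FALSE)
  }

  vd <- vapour_density(trace$temp_c, trace$rh_pct, formulation)
  seg <- trace$segment
  has_pre <- any(seg == "baseline_pre")
  has_post <- any(seg == "baseline_post")
  if (!has_pre && !has_post) stop("no baseline segment", call. = FALSE)

  win <- detect_resting_window(trace, rest_min_s, read_window_s, flat_sd_max)
  in_win <- seg == "animal" & trace$time_s >= win$start_s - 1e-9 &
    trace$time_s <= win$end_s + 1e-9
  vd_a <- mean(vd[in_win])

  if (has_pre && has_post) {
    vd_pre <- mean(vd[seg == "baseline_pre"])
    vd_post <- mean(vd[seg == "baseline_post"])
    if (abs(vd_pre - vd_post) > baseline_drift_tol_g_cm3) {
      warning("baseline drift exceeds tolerance (",
              signif(abs(vd_pre - vd_post), 3),
              " g cm^-3); interpolating baseline linearly in time",
              call. = FALSE)
      t_pre <- mean(trace$time_s[seg == "baseline_pre"])
      t_post <- mean(trace$time_s[seg == "baseline_post"])
      t_mid <- (win$start_s + win$end_s) / 2
      vd_i <- vd_pre + (vd_post - vd_pre) * (t_mid - t_pre) / (t_post - t_pre)
    } else {
      vd_i <- (vd_pre + vd_post) / 2
    }
  } else {
    warning("only one baseline segment present; using it alone",
            call. = FALSE)
    vd_i <- mean(vd[seg != "animal"])
  }

  ve <- flow_l_min_to_cm3_s(meta$flow_rate_l_min)
  mw <- ve * (vd_a - vd_i)
  valid <- TRUE
  if ((vd_a - vd_i) < -baseline_drift_tol_g_cm3) {
    warning("chamber vapour density below baseline beyond tolerance; ",
            "trial flagged invalid (baseline drift)", call. = FALSE)
    valid <- FALSE
  }

  sa <- meta$surface_area_cm2
  skin <- meta$skin_temp_c
  ec <- if (!is.null(sa) && !is.na(sa) && mw > 0) {
    area_specific_ewl(mw, sa)
  } else NA_real_
  res <- if (!is.na(ec) && !is.null(skin) && !is.na(skin) && ec > 0) {
    total_resistance(skin, vd_a, ec, formulation)
  } else NA_real_

  out <- data.frame(
    animal_id = meta$animal_id %||% NA_character_,
    species = meta$species %||% NA_character_,
    season = meta$season %||% NA_character_,
    sex = meta$sex %||% NA_character_,
    mass_g = meta$mass_g %||% NA_real_,
    skin_temp_c = skin %||% NA_real_,
    surface_area_cm2 = sa %||% NA_real_,
    vd_baseline_g_cm3 = vd_i,
    vd_animal_g_cm3 = vd_a,
    mw_g_s = mw,
    mw_g_h = mw * 3600,
    ec_g_cm2_s = ec,
    resistance_s_cm = res,
    rest_start_s = win$start_s,
    rest_end_s = win$end_s,
    valid = valid,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ewl_result", class(out))
  out
}

#' Area-specific evaporative water loss
#'
#' \eqn{E_c = M_w / SA}: total water flux expressed per unit body surface
#' area, giving a size-independent rate.
#'
#' @param mw_g_s Mass flow of water, g s^-1.
#' @param surface_area_cm2 Whole-animal surface area, cm^2 (> 0).
#' @return Area-specific EWL, g cm^-2 s^-1.
#' @export
area_specific_ewl <- function(mw_g_s, surface_area_cm2) {
  if (any(!is.finite(surface_area_cm2)) || any(surface_area_cm2 <= 0)) {
    stop("surface_area_cm2 must be positive", call. = FALSE)
  }
  mw_g_s / surface_area_cm2
}

#' Total resistance to water loss
#'
#' \eqn{R = (VD_s - VD_a) / E_c} in s cm^-1, where \eqn{VD_s} is the skin
#' vapour density, taken as the saturation vapour density at the measured
#' skin temperature, and \eqn{VD_a} is the chamber vapour density. High
#' resistance means low skin permeability.
#'
#' @param skin_temp_c Dorsal skin temperature at trial end, degC.
#' @param vd_animal_g_cm3 Chamber vapour density \eqn{VD_a}, g cm^-3.
#' @param ec_g_cm2_s Area-specific EWL \eqn{E_c}, g cm^-2 s^-1 (> 0).
#' @param formulation Saturation vapour pressure formulation.
#' @return Total resistance, s cm^-1. `NA` with a warning when the chamber
#'   is supersaturated relative to the skin (\eqn{VD_s < VD_a}), which
#'   indicates an invalid trial.
#' @export
total_resistance <- function(skin_temp_c, vd_animal_g_cm3, ec_g_cm2_s,
                             formulation = "buck1996") {
  if (any(!is.finite(ec_g_cm2_s)) || any(ec_g_cm2_s <= 0)) {
    stop("ec_g_cm2_s must be positive", call. = FALSE)
  }
  vd_s <- saturation_vapour_density(skin_temp_c, formulation)
  r <- (vd_s - vd_animal_g_cm3) / ec_g_cm2_s
  if (any(vd_s < vd_animal_g_cm3)) {
    warning("VD_s < VD_a: chamber supersaturated relative to skin; ",
            "resistance set to NA", call. = FALSE)
    r[vd_s < vd_animal_g_cm3] <- NA_real_
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
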