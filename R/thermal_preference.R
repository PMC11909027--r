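# Thermal preference: reduce repeated body temperatures measured on a
# thermal gradient to the set-point range (the central 50% of readings) and
# the preferred temperature (their mean).

.gradient_bounds_c <- c(20, 40)

#' Set-point range of gradient body temperatures
#'
#' The set-point range is the central 50% of an animal's repeated body
#' temperature readings: with \eqn{n} readings, the lowest and highest
#' \eqn{\lfloor n/4 \rfloor} are dropped by rank (stable sort, so ties keep
#' their input order) and the retained block defines the range. For the
#' nominal protocol of 12 hourly readings exactly 6 are retained; whenever
#' \eqn{4 | n} exactly half are retained, otherwise at most one extra
#' reading is kept. The bounds reported are the retained extremes (the
#' 25th/75th percentiles read off by rank).
#'
#' @param readings Numeric vector of body temperatures, degC, at least 4,
#'   within the gradient bounds \[20, 40\].
#' @return List with `lower_c`, `upper_c`, `central_values` (sorted),
#'   `n_total`, `n_central`.
#' @examples
#' set_point_range(1:12 + 20)  # retains ranks 4..9
#' @export
set_point_range <- function(readings) {
  if (!is.numeric(readings) || anyNA(readings)) {
    stop("readings must be numeric with no missing values", call. = FALSE)
  }
  n <- length(readings)
  if (n < 4L) {
    stop("at least 4 readings are required for a central-50% reduction",
         call. = FALSE)
  }
  b <- .gradient_bounds_c
  if (any(readings < b[1] | readings > b[2])) {
    stop(sprintf("readings outside gradient bounds [%g, %g] degC",
                 b[1], b[2]), call. = FALSE)
  }
  drop <- n %/% 4L
  srt <- readings[order(readings)]  # order() is stable
  central <- srt[(drop + 1L):(n - drop)]
  list(lower_c = central[1L], upper_c = central[length(central)],
       central_values = central, n_total = n, n_central = length(central))
}

#' Preferred temperature of one animal
#'
#' The mean of the set-point (central 50%) readings; one value per animal,
#' invariant to the order in which readings were taken.
#'
#' @inheritParams set_point_range
#' @return Preferred temperature, degC.
#' @examples
#' preferred_temperature(1:12 + 20)  # mean of ranks 4..9
#' @export
preferred_temperature <- function(readings) {
  mean(set_point_range(readings)$central_values)
}

#' Reduce a long body-temperature table to per-animal set-points
#'
#' Input is one row per reading (`animal_id`, `tb_c`, plus any grouping
#' columns such as `species`, `season`, `sex`, which are carried through).
#' Output is the per-animal summary used for preferred-temperature
#' analyses, plus the long table of retained central readings, which is the
#' natural input for a mixed model with animal identity as a random effect.
#'
#' @param df Data frame with columns `animal_id`, `tb_c` and optional
#'   grouping columns.
#' @return List with `summary` (per animal: `tpref_c`, `setpoint_low_c`,
#'   `setpoint_high_c`, `n_readings`) and `central` (long table of retained
#'   readings, column `tb_c`).
#' @export
reduce_tpref <- function(df) {
  if (!all(c("animal_id", "tb_c") %in% names(df))) {
    stop("df must have columns animal_id and tb_c", call. = FALSE)
  }
  keep <- intersect(c("animal_id", "species", "season", "sex"), names(df))
  ids <- unique(df$animal_id)
  summaries <- vector("list", length(ids))
  centrals <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$animal_id == ids[i], , drop = FALSE]
    spr <- set_point_range(rows$tb_c)
    meta <- rows[1L, keep, drop = FALSE]
    summaries[[i]] <- cbind(meta, data.frame(
      tpref_c = mean(spr$central_values),
      setpoint_low_c = spr$lower_c,
      setpoint_high_c = spr$upper_c,
      n_readings = spr$n_total,
      n_central = spr$n_central))
    centrals[[i]] <- cbind(meta[rep(1L, spr$n_central), , drop = FALSE],
                           data.frame(tb_c = spr$central_values))
  }
  summary <- do.call(rbind, summaries)
  central <- do.call(rbind, centrals)
  rownames(summary) <- rownames(central) <- NULL
  list(summary = summary, central = central)
}
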