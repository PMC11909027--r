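# Refuge occupancy: turn frame-classified time-lapse logs (one state every
# frame_interval_s seconds: humid refuge, dry refuge, or out in the open)
# into weighted occupancy summaries and humid-vs-dry preference tests.

.refuge_states <- c("humid", "dry", "open")

#' Treatment labels for the thermo-hydroregulation trials
#'
#' The three humidity-choice treatments, written `<humid refuge temp>H/<dry
#' refuge temp>D`: the dry refuge is held at 32 degC / 36.5% RH throughout
#' while the humid refuge (99% RH) is run at 32, 27 or 22 degC.
#' @export
refuge_treatments <- c("22H/32D", "27H/32D", "32H/32D")

#' Summarise a refuge-occupancy log
#'
#' Each scored frame contributes `frame_interval_s` seconds to its state's
#' total. Frames whose state is missing (`NA`) or `"unscorable"` are
#' dropped from every denominator and counted in `n_dropped`. The two
#' proportions returned are the ones that drive the preference analyses:
#' time in any refuge over total time, and time in the humid refuge over
#' refuge time; the raw durations are kept so downstream models can weight
#' by them.
#'
#' @param log Data frame with columns `time_s` and `state` (one of
#'   `"humid"`, `"dry"`, `"open"`).
#' @param frame_interval_s Time-lapse interval, s (default 10).
#' @return One-row data frame: `n_frames`, `n_dropped`, `t_total_s`,
#'   `t_refuge_s`, `t_humid_s`, `p_refuge`, `p_humid_given_refuge` (NA when
#'   no refuge time was observed).
#' @examples
#' log <- data.frame(time_s = seq(0, 50, 10),
#'                   state = c("humid", "humid", "dry", "open", "dry", "humid"))
#' summarize_occupancy(log)
#' @export
summarize_occupancy <- function(log, frame_interval_s = 10) {
  if (!all(c("time_s", "state") %in% names(log))) {
    stop("log must have columns time_s and state", call. = FALSE)
  }
  if (nrow(log) == 0L) stop("empty occupancy log", call. = FALSE)
  state <- as.character(log$state)
  drop <- is.na(state) | state == "unscorable"
  state <- state[!drop]
  bad <- setdiff(unique(state), .refuge_states)
  if (length(bad)) {
    stop("unknown state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(state)) stop("no scorable frames in log", call. = FALSE)
  n_humid <- sum(state == "humid")
  n_dry <- sum(state == "dry")
  n <- length(state)
  t_total <- n * frame_interval_s
  t_refuge <- (n_humid + n_dry) * frame_interval_s
  t_humid <- n_humid * frame_interval_s
  data.frame(
    n_frames = n,
    n_dropped = sum(drop),
    t_total_s = t_total,
    t_refuge_s = t_refuge,
    t_humid_s = t_humid,
    p_refuge = t_refuge / t_total,
    p_humid_given_refuge = if (t_refuge > 0) t_humid / t_refuge else NA_real_
  )
}

#' Test refuge humidity preference against 50:50
#'
#' One-sample test of equal proportions: is the proportion of refuge time
#' spent in the humid refuge different from 0.5 (no preference)? Durations
#' are converted back to frame counts (`duration / frame_interval_s`) and
#' each frame is treated as an independent Bernoulli trial, tested with the
#' chi-squared equal-proportions test with continuity correction
#' ([stats::prop.test()]). Estimates significantly above 0.5 indicate a
#' humid-refuge preference, below 0.5 a dry-refuge preference.
#'
#' Consecutive frames 10 s apart are not truly independent; the result
#' carries a `frames_assumed_independent` flag so downstream users see the
#' caveat. No autocorrelation correction is applied.
#'
#' @param t_humid_s Time in the humid refuge, s.
#' @param t_refuge_s Total refuge time, s (> 0).
#' @param frame_interval_s Time-lapse interval, s.
#' @return One-row data frame: `k_humid`, `n_refuge` (frame counts),
#'   `estimate`, `statistic` (chi-squared), `p_value`, `direction`
#'   (`"humid"`, `"dry"` or `"none"`), `frames_assumed_independent`.
#' @examples
#' equal_proportion_test(t_humid_s = 970, t_refuge_s = 1000,
#'                       frame_interval_s = 10)
#' @export
equal_proportion_test <- function(t_humid_s, t_refuge_s,
                                  frame_interval_s = 10) {
  if (!is.finite(t_refuge_s) || t_refuge_s <= 0) {
    stop("t_refuge_s must be positive: the humid-vs-dry preference is ",
         "undefined with no refuge time", call. = FALSE)
  }
  if (t_humid_s < 0 || t_humid_s > t_refuge_s) {
    stop("t_humid_s must lie in [0, t_refuge_s]", call. = FALSE)
  }
  k <- round(t_humid_s / frame_interval_s)
  n <- round(t_refuge_s / frame_interval_s)
  ht <- stats::prop.test(k, n, p = 0.5, alternative = "two.sided",
                         correct = TRUE)
  est <- unname(ht$estimate)
  data.frame(
    k_humid = k,
    n_refuge = n,
    estimate = est,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    direction = if (ht$p.value >= 0.05) "none" else
      if (est > 0.5) "humid" else "dry",
    frames_assumed_independent = TRUE
  )
}

#' Per-animal, per-treatment refuge summary table
#'
#' Splits a frame log by animal and treatment, summarises occupancy and
#' appends the humid-vs-dry equal-proportion test columns. This is the
#' tidy, weighted table a binomial mixed model consumes.
#'
#' @param df Data frame with columns `animal_id`, `treatment`, `time_s`,
#'   `state`; optional `species` is carried through.
#' @param frame_interval_s Time-lapse interval, s.
#' @return Data frame, one row per animal x treatment.
#' @export
refuge_summary_table <- function(df, frame_interval_s = 10) {
  need <- c("animal_id", "treatment", "time_s", "state")
  if (!all(need %in% names(df))) {
    stop("df must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$treatment)), refuge_treatments)
  if (length(bad)) {
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(refuge_treatments, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c("animal_id", "treatment", "species"), names(df))
  groups <- unique(df[, c("animal_id", "treatment"), drop = FALSE])
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- df[df$animal_id == groups$animal_id[i] &
                df$treatment == groups$treatment[i], , drop = FALSE]
    summ <- summarize_occupancy(sub, frame_interval_s)
    test <- if (summ$t_refuge_s > 0) {
      equal_proportion_test(summ$t_humid_s, summ$t_refuge_s,
                            frame_interval_s)
    } else {
      data.frame(k_humid = 0L, n_refuge = 0L, estimate = NA_real_,
                 statistic = NA_real_, p_value = NA_real_,
                 direction = NA_character_,
                 frames_assumed_independent = TRUE)
    }
    rows[[i]] <- cbind(sub[1L, keep, drop = FALSE], summ, test)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
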