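# Geometric surface-area estimation and body condition from linear body
# measurements. The whole animal is modelled as six single-ended cylinders
# (torso including head, tail, four legs); lengths and greatest widths are
# measured in mm with callipers, areas are reported in cm^2.

.part_cols <- list(
  torso = c("torso_l_mm", "torso_w_mm"),
  tail  = c("tail_l_mm", "tail_w_mm"),
  leg1  = c("leg1_l_mm", "leg1_w_mm"),
  leg2  = c("leg2_l_mm", "leg2_w_mm"),
  leg3  = c("leg3_l_mm", "leg3_w_mm"),
  leg4  = c("leg4_l_mm", "leg4_w_mm")
)

#' Surface area of a single-ended cylinder
#'
#' Lateral surface plus one end disc: \eqn{\pi w L + \pi (w/2)^2}, with the
#' measured greatest width \eqn{w} treated as the cylinder diameter. The
#' open end is the one that abuts the body, so each body part contributes
#' exactly one cap. Setting `capped = FALSE` drops the end disc (plain open
#' cylinder), for sensitivity analyses.
#'
#' @param length_mm Part length, mm (>= 0).
#' @param width_mm Greatest part width (diameter), mm (>= 0).
#' @param capped Include the single end disc (default TRUE).
#' @return Surface area, cm^2.
#' @examples
#' single_ended_cylinder_area(10, 10)  # 1.25 * pi = 3.927 cm^2
#' @export
single_ended_cylinder_area <- function(length_mm, width_mm, capped = TRUE) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("lengths and widths must be non-negative", call. = FALSE)
  }
  l_cm <- length_mm / 10
  w_cm <- width_mm / 10
  area <- pi * w_cm * l_cm
  if (capped) area <- area + pi * (w_cm / 2)^2
  area
}

#' Whole-animal surface area from the six-cylinder model
#'
#' Sums the single-ended-cylinder areas of the six body parts: torso
#' (snout to vent, including the head), tail and four legs. Torso
#' measurements are mandatory; a missing or `NA` tail or leg (e.g. a
#' regenerating tail recorded as zero) contributes zero area, with a
#' warning.
#'
#' @param morpho A named list, one-row data frame, or multi-row data frame
#'   with columns `torso_l_mm`, `torso_w_mm`, `tail_l_mm`, `tail_w_mm`,
#'   `leg1_l_mm`, `leg1_w_mm`, ..., `leg4_w_mm`.
#' @param capped Passed to [single_ended_cylinder_area()].
#' @return Numeric vector of surface areas, cm^2 (one per row).
#' @examples
#' total_surface_area(list(torso_l_mm = 60, torso_w_mm = 12,
#'                         tail_l_mm = 50, tail_w_mm = 6,
#'                         leg1_l_mm = 20, leg1_w_mm = 3,
#'                         leg2_l_mm = 20, leg2_w_mm = 3,
#'                         leg3_l_mm = 22, leg3_w_mm = 3,
#'                         leg4_l_mm = 22, leg4_w_mm = 3))
#' @export
total_surface_area <- function(morpho, capped = TRUE) {
  df <- as.data.frame(as.list(morpho), stringsAsFactors = FALSE)
  if (is.data.frame(morpho)) df <- morpho
  if (!all(.part_cols$torso %in% names(df)) ||
      anyNA(df[, .part_cols$torso])) {
    stop("torso_l_mm and torso_w_mm are required and must be non-missing",
         call. = FALSE)
  }
  total <- rep(0, nrow(df))
  missing_parts <- character(0)
  for (part in names(.part_cols)) {
    cols <- .part_cols[[part]]
    if (!all(cols %in% names(df))) {
      missing_parts <- c(missing_parts, part)
      next
    }
    l <- df[[cols[1]]]
    w <- df[[cols[2]]]
    na <- is.na(l) | is.na(w)
    if (any(na) && part != "torso") missing_parts <- c(missing_parts, part)
    l[na] <- 0
    w[na] <- 0
    total <- total + single_ended_cylinder_area(l, w, capped)
  }
  if (length(missing_parts)) {
    warning("part(s) treated as zero area: ",
            paste(unique(missing_parts), collapse = ", "), call. = FALSE)
  }
  total
}

#' Body condition as the mass/SVL ratio
#'
#' The body-condition index is the ratio of body mass (g) to snout--vent
#' length (mm); because ratios are non-normal it is also returned arcsine
#' square-root transformed, which requires the ratio to lie in \[0, 1\]
#' (it always does for geckos when mass is in g and SVL in mm).
#'
#' @param mass_g Body mass, g (>= 0).
#' @param svl_mm Snout--vent length, mm (> 0).
#' @return Data frame with columns `ratio` (g mm^-1) and `asin_sqrt`
#'   (radians).
#' @examples
#' body_condition(1.5, 50)  # ratio 0.03, asin(sqrt(0.03)) = 0.1741
#' @export
body_condition <- function(mass_g, svl_mm) {
  if (any(svl_mm <= 0)) stop("svl_mm must be positive", call. = FALSE)
  if (any(mass_g < 0)) stop("mass_g must be non-negative", call. = FALSE)
  ratio <- mass_g / svl_mm
  if (any(ratio > 1)) {
    stop("mass/SVL ratio exceeds 1; the arcsine square-root transform ",
         "expects mass in g and SVL in mm (ratio << 1)", call. = FALSE)
  }
  data.frame(ratio = ratio, asin_sqrt = asin(sqrt(ratio)))
}

#' Remove gravid females from a morphometrics table
#'
#' Gravid females carry egg mass that inflates the body-condition index,
#' so condition analyses exclude them. Removes exactly the rows whose
#' `gravid` flag is `TRUE`.
#'
#' @param df Data frame with a logical `gravid` column.
#' @return The filtered data frame.
#' @export
exclude_gravid <- function(df) {
  if (!"gravid" %in% names(df)) stop("no 'gravid' column", call. = FALSE)
  df[!isTRUE_vec(df$gravid), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
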