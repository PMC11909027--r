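# Psychrometric conversions: the substrate for every water-loss calculation.
# All pressures in kPa, absolute humidity in g m^-3, vapour density in g cm^-3.

# Physical constants, kept in one place so they can be swapped/audited.
.psychro_const <- list(
  r_w_j_kg_k    = 461.5,    # specific gas constant of water vapour
  kelvin_offset = 273.15,
  temp_min_c    = -40,
  temp_max_c    = 60
)

#' Validate an air state (temperature / relative humidity pair)
#'
#' Every psychrometric function funnels its inputs through this check.
#' Temperatures must lie in \[-40, 60\] degC (the range over which the
#' closed-form saturation vapour pressure approximations used here are
#' accurate) and relative humidity in \[0, 100\]%.
#'
#' @param temperature_c Air temperature, degC. Numeric vector.
#' @param relative_humidity_pct Relative humidity, percent. Numeric vector
#'   (recycled against `temperature_c`), or `NULL` to validate temperature
#'   only.
#' @return Invisibly, a data frame with the recycled, validated pair.
#' @export
air_state <- function(temperature_c, relative_humidity_pct = NULL) {
  if (!is.numeric(temperature_c) || anyNA(temperature_c)) {
    stop("temperature_c must be numeric with no missing values", call. = FALSE)
  }
  cc <- .psychro_const
  if (any(temperature_c < cc$temp_min_c | temperature_c > cc$temp_max_c)) {
    stop(sprintf("temperature_c outside supported range [%g, %g] degC",
                 cc$temp_min_c, cc$temp_max_c), call. = FALSE)
  }
  if (is.null(relative_humidity_pct)) {
    return(invisible(data.frame(temperature_c = temperature_c)))
  }
  if (!is.numeric(relative_humidity_pct) || anyNA(relative_humidity_pct)) {
    stop("relative_humidity_pct must be numeric with no missing values",
         call. = FALSE)
  }
  if (any(relative_humidity_pct < 0 | relative_humidity_pct > 100)) {
    stop("relative_humidity_pct must lie in [0, 100]", call. = FALSE)
  }
  st <- data.frame(temperature_c = temperature_c,
                   relative_humidity_pct = relative_humidity_pct)
  invisible(st)
}

#' Saturation vapour pressure of water
#'
#' Closed-form approximation to the saturation vapour pressure over liquid
#' water. The default is the Arden Buck (1996) equation,
#' \deqn{e_s(T) = 0.61121 \exp[(18.678 - T/234.5)\, T/(257.14 + T)]}{
#'   es(T) = 0.61121 exp((18.678 - T/234.5) T/(257.14 + T))}
#' with \eqn{T} in degC and \eqn{e_s} in kPa, which agrees with standard
#' meteorological tables to well within 0.1% over 0--50 degC. Buck (1981)
#' and the Goff--Gratch (1946) formulation (the basis of the classical
#' Smithsonian tables) are available as alternatives; all three agree to
#' ~0.1% over the biological range.
#'
#' @param temperature_c Air temperature, degC.
#' @param formulation One of `"buck1996"` (default), `"buck1981"`,
#'   `"goff_gratch"`.
#' @return Saturation vapour pressure, kPa.
#' @examples
#' saturation_vapour_pressure(32)   # ~4.76 kPa
#' saturation_vapour_pressure(0)    # ~0.611 kPa
#' @export
saturation_vapour_pressure <- function(temperature_c,
                                       formulation = c("buck1996", "buck1981",
                                                       "goff_gratch")) {
  air_state(temperature_c)
  formulation <- match.arg(formulation)
  t <- temperature_c
  switch(formulation,
    buck1996 = 0.61121 * exp((18.678 - t / 234.5) * (t / (257.14 + t))),
    buck1981 = 0.61121 * exp(17.502 * t / (240.97 + t)),
    goff_gratch = {
      tk <- t + .psychro_const$kelvin_offset
      ts <- 373.16  # steam point, K
      l10 <- -7.90298 * (ts / tk - 1) +
        5.02808 * log10(ts / tk) -
        1.3816e-7 * (10^(11.344 * (1 - tk / ts)) - 1) +
        8.1328e-3 * (10^(-3.49149 * (ts / tk - 1)) - 1) +
        log10(1013.246)
      10^l10 / 10  # hPa -> kPa
    })
}

#' Actual vapour pressure of moist air
#'
#' \eqn{VP = SVP(T) \times RH / 100}.
#'
#' @inheritParams saturation_vapour_pressure
#' @param relative_humidity_pct Relative humidity, percent.
#' @return Vapour pressure, kPa.
#' @examples
#' vapour_pressure(32, 36.5)  # ~1.74 kPa
#' @export
vapour_pressure <- function(temperature_c, relative_humidity_pct,
                            formulation = "buck1996") {
  st <- air_state(temperature_c, relative_humidity_pct)
  saturation_vapour_pressure(st$temperature_c, formulation) *
    st$relative_humidity_pct / 100
}

#' Vapour pressure deficit
#'
#' The drying power of the air: \eqn{VPD = SVP(T) - VP(T, RH)}. Zero at
#' saturation.
#'
#' @inheritParams vapour_pressure
#' @return Vapour pressure deficit, kPa (non-negative).
#' @examples
#' vapour_pressure_deficit(32, 36.5)  # ~3.02 kPa
#' vapour_pressure_deficit(25, 100)   # 0
#' @export
vapour_pressure_deficit <- function(temperature_c, relative_humidity_pct,
                                    formulation = "buck1996") {
  st <- air_state(temperature_c, relative_humidity_pct)
  svp <- saturation_vapour_pressure(st$temperature_c, formulation)
  svp - svp * st$relative_humidity_pct / 100
}

#' Absolute humidity (water vapour density per cubic metre)
#'
#' Converts vapour pressure to vapour mass density through the ideal gas law
#' for water vapour, \eqn{AH = VP / (R_w T_K)} with
#' \eqn{R_w = 461.5\ \mathrm{J\,kg^{-1}\,K^{-1}}} and
#' \eqn{T_K = T + 273.15}.
#'
#' @inheritParams vapour_pressure
#' @return Absolute humidity, g m^-3.
#' @examples
#' absolute_humidity(32, 36.5)  # ~12.3 g m^-3
#' @export
absolute_humidity <- function(temperature_c, relative_humidity_pct,
                              formulation = "buck1996") {
  st <- air_state(temperature_c, relative_humidity_pct)
  vp_pa <- vapour_pressure(st$temperature_c, st$relative_humidity_pct,
                           formulation) * 1000
  cc <- .psychro_const
  # kg m^-3 -> g m^-3
  vp_pa / (cc$r_w_j_kg_k * (st$temperature_c + cc$kelvin_offset)) * 1000
}

#' Saturation vapour density
#'
#' Absolute humidity at 100% relative humidity, expressed per cubic
#' centimetre -- the unit in which vapour densities enter the open-flow
#' water-loss equations. Evaluated at the skin temperature this is the skin
#' vapour density \eqn{VD_s}.
#'
#' @inheritParams saturation_vapour_pressure
#' @return Saturation vapour density, g cm^-3.
#' @examples
#' saturation_vapour_density(32)  # ~3.38e-05 g cm^-3
#' @export
saturation_vapour_density <- function(temperature_c,
                                      formulation = "buck1996") {
  absolute_humidity(temperature_c, 100, formulation) / 1e6
}

#' Vapour density of moist air
#'
#' Absolute humidity converted to g cm^-3 (\eqn{VD = AH \times 10^{-6}}),
#' the unit used for \eqn{VD_a} and \eqn{VD_i} in the open-flow equations.
#'
#' @inheritParams vapour_pressure
#' @return Vapour density, g cm^-3.
#' @export
vapour_density <- function(temperature_c, relative_humidity_pct,
                           formulation = "buck1996") {
  absolute_humidity(temperature_c, relative_humidity_pct, formulation) / 1e6
}

#' Full psychrometric state of an air sample
#'
#' One row per (temperature, humidity) pair with all derived quantities:
#' saturation and actual vapour pressure, vapour pressure deficit, absolute
#' humidity and vapour density.
#'
#' @inheritParams vapour_pressure
#' @return A data frame with columns `temperature_c`,
#'   `relative_humidity_pct`, `svp_kpa`, `vp_kpa`, `vpd_kpa`, `ah_g_m3`,
#'   `vd_g_cm3`.
#' @examples
#' psychrometric_state(c(32, 27, 22), 99)
#' @export
psychrometric_state <- function(temperature_c, relative_humidity_pct,
                                formulation = "buck1996") {
  st <- air_state(temperature_c, relative_humidity_pct)
  svp <- saturation_vapour_pressure(st$temperature_c, formulation)
  vp <- svp * st$relative_humidity_pct / 100
  ah <- absolute_humidity(st$temperature_c, st$relative_humidity_pct,
                          formulation)
  data.frame(
    temperature_c = st$temperature_c,
    relative_humidity_pct = st$relative_humidity_pct,
    svp_kpa = svp,
    vp_kpa = vp,
    vpd_kpa = svp - vp,
    ah_g_m3 = ah,
    vd_g_cm3 = ah / 1e6
  )
}
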