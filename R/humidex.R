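# Humidex apparent-temperature index and a-priori exposure categories.
#
# Constants are the Masterton-Richardson / Environment Canada form, pinned in
# one place so an alternative variant can be swapped in deliberately.
.humidex_const <- list(
  weight = 0.5555,   # weight on the vapour-pressure excess (index units / hPa)
  e0     = 6.11,     # saturation vapour pressure at the triple point (hPa)
  k      = 5417.7530, # Clausius-Clapeyron coefficient (K)
  t0     = 273.16    # triple-point temperature (K)
)

# Magnus approximation constants for the RH -> dew point conversion.
.magnus_const <- list(a = 17.625, b = 243.04)

#' Dew point from air temperature and relative humidity
#'
#' Inverts the Magnus saturation-vapour-pressure approximation (a = 17.625,
#' b = 243.04 degC) to convert mean relative humidity into a dew-point
#' temperature. Used when the daily weather grid carries relative humidity
#' rather than dew point.
#'
#' @param t_air Air temperature in degrees Celsius.
#' @param rh Relative humidity in percent, in (0, 100].
#' @return Dew-point temperature in degrees Celsius; never exceeds `t_air`,
#'   and equals `t_air` at saturation (`rh = 100`).
#' @examples
#' dewpoint_from_rh(30, 50)   # about 18.4
#' dewpoint_from_rh(20, 100)  # exactly 20
#' @export
dewpoint_from_rh <- function(t_air, rh) {
  if (!all(is.finite(t_air))) stop("t_air must be finite")
  if (!all(is.finite(rh)) || any(rh <= 0) || any(rh > 100)) {
    stop("rh must be in (0, 100]")
  }
  a <- .magnus_const$a
  b <- .magnus_const$b
  gamma <- log(rh / 100) + a * t_air / (b + t_air)
  b * gamma / (a - gamma)
}

#' Humidex apparent temperature
#'
#' Combines air temperature and dew point into the Humidex index:
#' `H = T + 0.5555 * (e - 10)` where `e` is the dew-point vapour pressure in
#' hPa from the Clausius-Clapeyron relation
#' `e = 6.11 * exp(5417.753 * (1/273.16 - 1/T_dew[K]))`.
#' Unitless, but on a degrees-Celsius-like scale; strictly increasing in both
#' arguments.
#'
#' A dew point slightly above air temperature (by at most 0.5 degC, as can
#' arise from rounding in gridded products) triggers a warning; larger
#' violations are an error.
#'
#' @param t_air Air temperature, degC.
#' @param t_dew Dew-point temperature, degC.
#' @return Humidex index value(s).
#' @examples
#' humidex(30, 20)  # about 37.6
#' @export
humidex <- function(t_air, t_dew) {
  if (!all(is.finite(t_air)) || !all(is.finite(t_dew))) {
    stop("humidex: inputs must be finite")
  }
  excess <- t_dew - t_air
  if (any(excess > 0.5)) {
    stop("humidex: dew point exceeds air temperature by more than 0.5 degC")
  }
  if (any(excess > 0)) {
    warning("humidex: dew point slightly above air temperature (<= 0.5 degC); ",
            "treating as rounding noise")
  }
  cc <- .humidex_const
  e <- cc$e0 * exp(cc$k * (1 / cc$t0 - 1 / (t_dew + cc$t0)))
  t_air + cc$weight * (e - 10)
}

#' Humidex exposure category labels
#'
#' The a-priori exposure categories used throughout: `<25`, `25-29`, `30-33`,
#' `>=34`, derived from a Humidex-based occupational heat response plan.
#'
#' @return Character vector of the four category labels, reference first.
#' @export
humidex_categories <- function() c("<25", "25-29", "30-33", ">=34")

#' Categorise a Humidex value
#'
#' Assigns each finite Humidex value to one of the a-priori categories.
#' The printed integer labels are realised as half-open intervals
#' `[-Inf, 25)`, `[25, 30)`, `[30, 34)`, `[34, Inf)` so that every real value
#' is classified exactly once.
#'
#' @param h Numeric vector of Humidex values.
#' @return Factor with levels `humidex_categories()` (reference `<25` first).
#' @examples
#' categorize_humidex(c(24.99, 25, 29.9, 30, 33.9, 34))
#' @export
categorize_humidex <- function(h) {
  if (!all(is.finite(h))) stop("categorize_humidex: h must be finite")
  cut(h, breaks = c(-Inf, 25, 30, 34, Inf), right = FALSE,
      labels = humidex_categories())
}
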