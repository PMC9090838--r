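#' Saturation vapour pressure (Tetens)
#'
#' FAO-56 Tetens form `e0(T) = 0.6108 * exp(17.27 T / (T + 237.3))`.
#'
#' @param T Air temperature, degrees C. Must lie in \[-60, 60\].
#' @return Saturation vapour pressure in kPa; strictly increasing in `T`.
#' @export
saturation_vapor_pressure <- function(T) {
  if (any(!is.finite(T)) || any(T < -60) || any(T > 60)) {
    stop("temperature outside the physically plausible range [-60, 60] degC",
         call. = FALSE)
  }
  0.6108 * exp(17.27 * T / (T + 237.3))
}

#' Actual vapour pressure from mean relative humidity
#'
#' `ea = RHmean/100 * (e0(Tmax) + e0(Tmin)) / 2`, with `e0` the Tetens
#' saturation curve.
#'
#' @param RHmean Daily mean relative humidity, percent (0--100).
#' @param Tx,Tn Daily maximum and minimum temperature, degrees C.
#' @return Actual vapour pressure in kPa.
#' @export
actual_vapor_pressure <- function(RHmean, Tx, Tn) {
  if (any(RHmean < 0) || any(RHmean > 100)) {
    stop("`RHmean` must lie in [0, 100] percent", call. = FALSE)
  }
  if (any(Tn > Tx)) stop("`Tn` must not exceed `Tx`", call. = FALSE)
  (RHmean / 100) *
    (saturation_vapor_pressure(Tx) + saturation_vapor_pressure(Tn)) / 2
}

#' Wind speed height correction to 2 m
#'
#' Power-law profile `V = V_H * (Z / Z_H)^alpha` converting wind measured at
#' anemometer height (10 m by observing convention) to the 2 m reference
#' height used by crop models. The exponent alpha = 0.16 is the profile
#' index for the plateau stations this package targets.
#'
#' @param V_H Wind speed at measurement height, m/s (non-negative).
#' @param Z Target height, m (default 2).
#' @param Z_H Measurement height, m (default 10).
#' @param alpha Wind-profile exponent (default 0.16).
#' @return Wind speed at height `Z`, m/s.
#' @export
wind_at_2m <- function(V_H, Z = 2, Z_H = 10, alpha = 0.16) {
  if (any(V_H < 0)) stop("wind speed must be non-negative", call. = FALSE)
  V_H * (Z / Z_H)^alpha
}
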