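#' Extraterrestrial radiation and astronomical daylength
#'
#' Computes the maximum possible daily solar radiation at the top of the
#' atmosphere (`Ra_max`) and the astronomical daylength `N` for a given
#' latitude and day of year, using the FAO-56 formulation: solar declination,
#' sunset hour angle and the inverse relative Earth--Sun distance.
#'
#' `Ra_max` is returned in kJ/m2/day, the working radiation unit of the
#' package (seasonal totals are reported in MJ/m2 at output boundaries).
#'
#' @param latitude Latitude in decimal degrees, in \[-90, 90\].
#' @param day_of_year Integer day of year, 1--366. Vectorised; recycled
#'   against `latitude`.
#' @return A list with components `Ra_max` (kJ/m2/day) and `N` (hours).
#'   Under polar night `Ra_max` is 0 and `N` is 0; under polar day `N` is 24.
#' @examples
#' extraterrestrial_radiation(29.65, 172)
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("`latitude` must be within [-90, 90] degrees", call. = FALSE)
  }
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) || any(day_of_year > 366)) {
    stop("`day_of_year` must be within [1, 366]", call. = FALSE)
  }
  phi <- latitude * pi / 180
  J <- day_of_year
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  # clamp the hour-angle argument for polar day/night
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))
  # Gsc = 0.0820 MJ/m2/min; result converted MJ -> kJ
  Ra_MJ <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(Ra_max = pmax(0, Ra_MJ) * 1000, N = 24 * ws / pi)
}

#' Angstrom-Prescott radiation from relative sunshine duration
#'
#' Converts observed sunshine hours into daily global radiation as a linear
#' function of relative sunshine duration:
#' `Ra = Ra_max * (a + b * n/N)`.
#' The default coefficients a = 0.27 and b = 0.55 are the values recommended
#' for high-altitude continental stations on the Qinghai--Tibet Plateau.
#'
#' When `N = 0` (polar night) and `n = 0` the overcast limit `a * Ra_max`
#' is returned by convention; `n > 0` with `N = 0` is a data error.
#'
#' @param n Observed sunshine duration, hours.
#' @param N Astronomical daylength, hours (see
#'   [extraterrestrial_radiation()]).
#' @param Ra_max Extraterrestrial radiation, kJ/m2/day.
#' @param a,b Angstrom coefficients (fractions of `Ra_max`).
#' @return Daily global radiation `Ra` in kJ/m2/day, guaranteed to lie in
#'   `[a * Ra_max, (a + b) * Ra_max]`.
#' @export
angstrom_radiation <- function(n, N, Ra_max, a = 0.27, b = 0.55) {
  if (a <= 0 || b <= 0) stop("Angstrom coefficients must be positive", call. = FALSE)
  if (any(n < 0)) stop("sunshine duration `n` must be non-negative", call. = FALSE)
  if (any(N == 0 & n > 0)) {
    stop("sunshine recorded on a day with zero astronomical daylength", call. = FALSE)
  }
  if (any(n > N + 1e-9)) {
    stop("sunshine duration exceeds astronomical daylength", call. = FALSE)
  }
  frac <- ifelse(N > 0, n / N, 0)
  Ra_max * (a + b * frac)
}
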