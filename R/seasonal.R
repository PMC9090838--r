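#' Growing-season climate summary for one station-year
#'
#' Summarises derived daily weather over a day-of-year window: means of
#' Tave, Tmax, Tmin and the diurnal range; effective accumulated
#' temperature `EAT = sum(max(Tave, 0))` over the window (base 0 degC);
#' seasonal radiation total `RA` in MJ/m2; and the annual accumulated
#' temperature above 0 degC (`annual_AT0`), the quantity used for
#' temperature zoning.
#'
#' @param daily Derived daily records for a single station-year
#'   ([derive_daily()] output).
#' @param window Integer vector `c(start_doy, end_doy)`, inclusive.
#' @return One-row data.frame with columns `station_id, year, start_doy,
#'   end_doy, tave, tmax, tmin, tdr, EAT, RA, annual_AT0, n_days`.
#' @export
seasonal_summary <- function(daily, window) {
  stopifnot(length(window) == 2)
  if (window[2] < window[1]) stop("empty seasonal window", call. = FALSE)
  yr <- unique(daily$year)
  if (length(yr) != 1) stop("`daily` must cover a single year", call. = FALSE)
  sel <- daily$doy >= window[1] & daily$doy <= window[2]
  if (!any(sel)) stop("seasonal window contains no records", call. = FALSE)
  w <- daily[sel, , drop = FALSE]
  data.frame(
    station_id = daily$station_id[1],
    year = yr,
    start_doy = as.integer(window[1]),
    end_doy = as.integer(window[2]),
    tave = mean(w$tave),
    tmax = mean(w$tmax),
    tmin = mean(w$tmin),
    tdr = mean(w$tdr),
    EAT = sum(pmax(w$tave, 0)),
    RA = sum(w$Ra) / 1000,                # kJ -> MJ at the reporting boundary
    annual_AT0 = sum(pmax(daily$tave, 0)),
    n_days = nrow(w),
    stringsAsFactors = FALSE
  )
}
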