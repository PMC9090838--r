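#' Read a raw station weather archive
#'
#' Reads delimited text with one row per station-day and columns
#' `station_id, date, tave, tmax, tmin, sunshine_h, wind10, rh, precip`
#' (`date` in ISO-8601). Column order is free; names are matched.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @return A data.frame with the columns above, `date` parsed to `Date`.
#' @export
read_station_weather <- function(path, sep = ",") {
  cols <- c("station_id", "date", "tave", "tmax", "tmin",
            "sunshine_h", "wind10", "rh", "precip")
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop("weather file lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[cols]
  x$date <- as.Date(x$date)
  x$station_id <- as.character(x$station_id)
  x
}

#' Read station metadata
#'
#' Columns: `station_id, name, lat, lon, elev, variety`.
#'
#' @param path Path to the delimited metadata file.
#' @param sep Field separator (default comma).
#' @return A data.frame, one row per station.
#' @export
read_station_meta <- function(path, sep = ",") {
  cols <- c("station_id", "name", "lat", "lon", "elev", "variety")
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop("metadata file lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[cols]
  x$station_id <- as.character(x$station_id)
  if (any(x$lat < -90 | x$lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(x$elev < 0)) stop("elevation must be non-negative", call. = FALSE)
  x
}

#' Derive simulation-ready daily weather quantities
#'
#' Takes one station's raw daily records plus its latitude and derives the
#' quantities the simulator and the seasonal statistics need: day of year,
#' extraterrestrial radiation and daylength, Angstrom-Prescott global
#' radiation `Ra` (kJ/m2/day), actual vapour pressure `ea` (kPa), 2-m wind
#' `wind2` (m/s) and the temperature diurnal range `tdr` (degC).
#'
#' Missing `tave` is imputed as `(tmax + tmin)/2`. Records that remain
#' unusable (missing tmax/tmin, inverted extremes, humidity outside
#' \[0, 100\], sunshine exceeding daylength, negative wind) are dropped;
#' the number dropped is attached as attribute `n_excluded` and reported
#' via a message when positive.
#'
#' @param raw Data.frame as returned by [read_station_weather()] (single
#'   station).
#' @param latitude Station latitude, decimal degrees.
#' @param angstrom_a,angstrom_b Angstrom coefficients.
#' @return The input with derived columns `doy, year, Ra_max, N, Ra, ea,
#'   wind2, tdr` appended, invalid rows removed.
#' @export
derive_daily <- function(raw, latitude, angstrom_a = 0.27, angstrom_b = 0.55) {
  x <- raw
  x$year <- as.integer(format(x$date, "%Y"))
  x$doy <- as.integer(format(x$date, "%j"))

  # imputation: tave from the daily extremes when absent
  need <- is.na(x$tave) & !is.na(x$tmax) & !is.na(x$tmin)
  x$tave[need] <- (x$tmax[need] + x$tmin[need]) / 2

  ast <- extraterrestrial_radiation(latitude, x$doy)
  x$Ra_max <- ast$Ra_max
  x$N <- ast$N
  # clip sub-resolution sunshine overshoot (rounding in archives), reject gross
  x$sunshine_h <- pmin(x$sunshine_h, x$N)

  bad <- is.na(x$tmax) | is.na(x$tmin) | is.na(x$tave) |
    x$tmin > x$tmax | x$tave < x$tmin - 1e-9 | x$tave > x$tmax + 1e-9 |
    is.na(x$sunshine_h) | x$sunshine_h < 0 |
    is.na(x$rh) | x$rh < 0 | x$rh > 100 |
    is.na(x$wind10) | x$wind10 < 0
  n_excluded <- sum(bad)
  if (n_excluded > 0) {
    message(sprintf("derive_daily: excluded %d unusable record(s)", n_excluded))
    x <- x[!bad, , drop = FALSE]
  }

  x$Ra <- angstrom_radiation(x$sunshine_h, x$N, x$Ra_max,
                             a = angstrom_a, b = angstrom_b)
  x$ea <- actual_vapor_pressure(x$rh, x$tmax, x$tmin)
  x$wind2 <- wind_at_2m(x$wind10)
  x$tdr <- x$tmax - x$tmin
  attr(x, "n_excluded") <- n_excluded
  x
}

#' Write and read simulator weather files
#'
#' Plain-text weather tables in the column convention of CABO crop-model
#' weather files: `station, year, doy, irrad` (kJ/m2/day), `tmin, tmax`
#' (degC), `vap` (kPa), `wind` (2-m wind, m/s), `precip` (mm). Values are
#' written at fixed precision (radiation 1 decimal, temperatures and the
#' rest 3 decimals) and round-trip bit-comparably at that precision.
#'
#' @param daily Data.frame from [derive_daily()].
#' @param path Output path.
#' @return `write_sim_weather` returns `path` invisibly;
#'   `read_sim_weather` returns the parsed data.frame.
#' @export
write_sim_weather <- function(daily, path) {
  out <- data.frame(
    station = daily$station_id,
    year    = daily$year,
    doy     = daily$doy,
    irrad   = round(daily$Ra, 1),
    tmin    = round(daily$tmin, 3),
    tmax    = round(daily$tmax, 3),
    vap     = round(daily$ea, 3),
    wind    = round(daily$wind2, 3),
    precip  = round(daily$precip, 3)
  )
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_weather
#' @export
read_sim_weather <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  x$station <- as.character(x$station)
  x
}
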