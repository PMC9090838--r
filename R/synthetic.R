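#' Configuration for the synthetic alpine weather generator
#'
#' Defaults emulate 40-year daily archives at high-altitude plateau
#' stations: a seasonal temperature harmonic whose level falls with
#' elevation, cross-correlated AR(1) day-to-day anomalies of Tmax and
#' Tmin, a station-specific diurnal range, sunshine-fraction variability,
#' and configurable linear trends (warming defaults 0.33 and 0.47 degC
#' per decade for Tmax and Tmin; a mild sunshine decline produces a
#' dimming radiation trend). See the methods vignette for the rationale
#' behind each default.
#'
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param n_stations Number of stations.
#' @param years Integer vector of simulated years.
#' @param lat_range,elev_range Uniform sampling ranges for station
#'   latitude (deg N) and elevation (m).
#' @param t_ann_at_ref Annual-mean temperature at `elev_ref` (degC).
#' @param elev_ref Reference elevation (m) for `t_ann_at_ref`.
#' @param lapse_rate Temperature decrease per km of elevation (degC/km).
#' @param lat_ref,lat_gradient Annual-mean temperature increases by
#'   `lat_gradient` degC per degree of latitude south of `lat_ref`
#'   (southern valleys are warmer, which keeps the warm-climate variety
#'   in thermally suitable territory).
#' @param t_amplitude Annual harmonic amplitude (degC).
#' @param t_peak_doy Day of year of the seasonal temperature peak.
#' @param tdr_range Uniform range of station-mean diurnal range (degC).
#' @param tdr_amplitude Seasonal amplitude of the diurnal range (degC).
#' @param ar_phi AR(1) coefficient of daily temperature anomalies.
#' @param ar_sigma Innovation standard deviation (degC).
#' @param ar_cross Cross-correlation of Tmax and Tmin innovations.
#' @param trend_tmax,trend_tmin Imposed linear trends, degC per decade.
#' @param sun_mean,sun_sd Mean and day-to-day s.d. of the sunshine
#'   fraction n/N.
#' @param sun_station_sd Between-station s.d. of the mean sunshine
#'   fraction.
#' @param trend_sun Sunshine-fraction trend per decade (negative =
#'   dimming).
#' @param rh_mean,rh_sd Relative-humidity distribution (percent).
#' @param wind_meanlog,wind_sdlog Log-normal parameters of 10-m wind.
#' @param precip_wet_prob,precip_shape,precip_scale Daily precipitation
#'   occurrence probability and wet-day gamma parameters (mm).
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(seed,
                               n_stations = 12,
                               years = 1978:2017,
                               lat_range = c(28, 38),
                               elev_range = c(2500, 3600),
                               t_ann_at_ref = 9.0,
                               elev_ref = 2500,
                               lapse_rate = 4.5,
                               lat_ref = 33,
                               lat_gradient = 0.45,
                               t_amplitude = 10.5,
                               t_peak_doy = 197,
                               tdr_range = c(10.5, 15),
                               tdr_amplitude = 1.5,
                               ar_phi = 0.7,
                               ar_sigma = 2.0,
                               ar_cross = 0.6,
                               trend_tmax = 0.33,
                               trend_tmin = 0.47,
                               sun_mean = 0.55,
                               sun_sd = 0.18,
                               sun_station_sd = 0.03,
                               trend_sun = -0.008,
                               rh_mean = 55,
                               rh_sd = 12,
                               wind_meanlog = log(2),
                               wind_sdlog = 0.4,
                               precip_wet_prob = 0.35,
                               precip_shape = 0.8,
                               precip_scale = 8) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(years) < 1) stop("need at least one year", call. = FALSE)
  if (abs(ar_phi) >= 1) stop("`ar_phi` must lie in (-1, 1)", call. = FALSE)
  if (ar_sigma <= 0) stop("`ar_sigma` must be positive", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "weather_gen_config"
  cfg
}

#' Generate a synthetic multi-station weather archive
#'
#' Produces a raw weather table in the station input schema
#' (`station_id, date, tave, tmax, tmin, sunshine_h, wind10, rh, precip`)
#' plus matching station metadata (`station_id, name, lat, lon, elev,
#' variety`; varieties are assigned by latitude band, mirroring the
#' planting geography: Chaiqing-1 north of 34 degN, Zangqing-2000 for
#' 30--34 degN, Diqing-1 south of 30 degN). Output is deterministic in
#' the seed, daily `tmin <= tave <= tmax` always holds (inverted draws
#' are order-repaired by swapping), and sunshine hours never exceed the
#' astronomical daylength.
#'
#' @param config A [weather_gen_config()].
#' @return List with data.frames `weather` and `meta`.
#' @export
gen_station_weather <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  set.seed(config$seed)
  cfg <- config

  dates <- seq(as.Date(sprintf("%d-01-01", min(cfg$years))),
               as.Date(sprintf("%d-12-31", max(cfg$years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  nd <- length(dates)
  # decades since record midpoint, for imposing trends
  dec <- (yr + (doy - 0.5) / 365.25 - mean(range(cfg$years)) - 0.5) / 10

  meta <- data.frame(
    station_id = sprintf("SYN%03d", seq_len(cfg$n_stations)),
    name = sprintf("synthetic-%03d", seq_len(cfg$n_stations)),
    lat = stats::runif(cfg$n_stations, cfg$lat_range[1], cfg$lat_range[2]),
    lon = stats::runif(cfg$n_stations, 85, 103),
    elev = stats::runif(cfg$n_stations, cfg$elev_range[1], cfg$elev_range[2]),
    stringsAsFactors = FALSE
  )
  meta$variety <- ifelse(meta$lat >= 34, "Chaiqing-1",
                         ifelse(meta$lat >= 30, "Zangqing-2000", "Diqing-1"))

  # station-level offsets drawn before the daily streams
  tdr_mean <- stats::runif(cfg$n_stations, cfg$tdr_range[1], cfg$tdr_range[2])
  sun_station <- stats::rnorm(cfg$n_stations, cfg$sun_mean, cfg$sun_station_sd)

  per_station <- vector("list", cfg$n_stations)
  for (s in seq_len(cfg$n_stations)) {
    t_ann <- cfg$t_ann_at_ref -
      cfg$lapse_rate * (meta$elev[s] - cfg$elev_ref) / 1000 +
      cfg$lat_gradient * (cfg$lat_ref - meta$lat[s])
    seasonal <- t_ann +
      cfg$t_amplitude * cos(2 * pi * (doy - cfg$t_peak_doy) / 365.25)
    tdr_seasonal <- tdr_mean[s] +
      cfg$tdr_amplitude * cos(2 * pi * (doy - 15) / 365.25)

    # cross-correlated AR(1) anomalies for the daily extremes
    z1 <- stats::rnorm(nd); z2 <- stats::rnorm(nd)
    e_max <- cfg$ar_sigma * z1
    e_min <- cfg$ar_sigma * (cfg$ar_cross * z1 +
                               sqrt(1 - cfg$ar_cross^2) * z2)
    a_max <- as.numeric(stats::filter(e_max, cfg$ar_phi, method = "recursive"))
    a_min <- as.numeric(stats::filter(e_min, cfg$ar_phi, method = "recursive"))

    tmax <- seasonal + tdr_seasonal / 2 + a_max + cfg$trend_tmax * dec
    tmin <- seasonal - tdr_seasonal / 2 + a_min + cfg$trend_tmin * dec
    inverted <- tmin > tmax
    if (any(inverted)) {           # order repair keeps the daily invariant
      tmp <- tmax[inverted]
      tmax[inverted] <- tmin[inverted]
      tmin[inverted] <- tmp
    }
    tave <- (tmax + tmin) / 2

    N <- extraterrestrial_radiation(meta$lat[s], doy)$N
    sun_frac <- pmin(pmax(stats::rnorm(nd, sun_station[s] + cfg$trend_sun * dec,
                                       cfg$sun_sd), 0), 1)
    rh <- pmin(pmax(stats::rnorm(nd, cfg$rh_mean, cfg$rh_sd), 3), 98)
    wind10 <- stats::rlnorm(nd, cfg$wind_meanlog, cfg$wind_sdlog)
    wet <- stats::runif(nd) < cfg$precip_wet_prob
    precip <- ifelse(wet,
                     stats::rgamma(nd, cfg$precip_shape, scale = cfg$precip_scale),
                     0)

    per_station[[s]] <- data.frame(
      station_id = meta$station_id[s],
      date = dates,
      tave = round(tave, 2),
      tmax = round(tmax, 2),
      tmin = round(tmin, 2),
      sunshine_h = round(sun_frac * N, 2),
      wind10 = round(wind10, 2),
      rh = round(rh, 1),
      precip = round(precip, 2),
      stringsAsFactors = FALSE
    )
  }
  list(weather = do.call(rbind, per_station), meta = meta)
}

#' Configuration for the synthetic yield-climate panel generator
#'
#' @param seed Integer seed.
#' @param n Number of panel rows.
#' @param beta Named numeric vector of true coefficients over the
#'   first-difference predictors (`dTave, dTmax, dTmin, dEAT, dTDR,
#'   dRA`); defaults to a radiation-only effect of 2.34 kg/ha per MJ/m2.
#' @param sigma Covariance matrix of the predictors (default diagonal
#'   with realistic inter-annual difference scales: 0.5/0.6/0.5 degC for
#'   the temperatures, 60 degC day for dEAT, 0.6 degC for dTDR,
#'   120 MJ/m2 for dRA).
#' @param noise_sd Residual s.d. of dYp, kg/ha.
#' @return A list of class `panel_gen_config`.
#' @export
panel_gen_config <- function(seed,
                             n = 500,
                             beta = c(dTave = 0, dTmax = 0, dTmin = 0,
                                      dEAT = 0, dTDR = 0, dRA = 2.34),
                             sigma = diag(c(0.5, 0.6, 0.5, 60, 0.6, 120)^2),
                             noise_sd = 100) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  preds <- c("dTave", "dTmax", "dTmin", "dEAT", "dTDR", "dRA")
  beta_full <- stats::setNames(numeric(6), preds)
  beta_full[names(beta)] <- beta
  dimnames(sigma) <- list(preds, preds)
  cfg <- list(seed = seed, n = n, beta = beta_full, sigma = sigma,
              noise_sd = noise_sd, predictors = preds)
  class(cfg) <- "panel_gen_config"
  cfg
}

#' Generate a synthetic first-difference yield-climate panel
#'
#' Draws predictor rows from a multivariate normal with the configured
#' covariance and builds `dYp = X beta + eps`. The true coefficients are
#' attached as attribute `truth`.
#'
#' @param config A [panel_gen_config()].
#' @return Data.frame with columns `zone, station_id, year, dYp` and the
#'   six predictors.
#' @export
gen_yield_panel <- function(config) {
  stopifnot(inherits(config, "panel_gen_config"))
  set.seed(config$seed)
  ev <- eigen(config$sigma, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(ev$values))) {
    stop("predictor covariance must be positive semi-definite", call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  Z <- matrix(stats::rnorm(config$n * 6), config$n, 6)
  X <- Z %*% t(L)
  colnames(X) <- config$predictors
  dYp <- as.numeric(X %*% config$beta) +
    stats::rnorm(config$n, 0, config$noise_sd)
  out <- data.frame(zone = "SYN", station_id = "SYN001",
                    year = seq_len(config$n), dYp = dYp, X,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- config$beta
  out
}
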