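# Shared fixtures, built in code.

# A constant-weather station-year: every day identical, which makes
# phenology and seasonal sums hand-computable.
constant_weather <- function(tave = 15, tdr = 12, Ra = 20000, N = 13,
                             doys = 1:330) {
  data.frame(
    doy = doys,
    tave = tave,
    tmax = tave + tdr / 2,
    tmin = tave - tdr / 2,
    Ra = Ra,
    N = N
  )
}

# One synthetic QTP-like station-year of derived weather via the
# generator + preprocessing chain (cached per seed within a test file).
synthetic_station_year <- function(seed = 101, year = 2005) {
  cfg <- weather_gen_config(seed = seed, n_stations = 1, years = year)
  arc <- gen_station_weather(cfg)
  d <- derive_daily(arc$weather, arc$meta$lat[1])
  list(daily = d, meta = arc$meta)
}

# Independent FAO-56 oracle for extraterrestrial radiation, written as a
# literal step-by-step transcription, separate from the production code.
fao56_oracle <- function(lat_deg, J) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * J)
  delta <- 0.409 * sin(2 * pi / 365 * J - 1.39)
  ws <- acos(-tan(phi) * tan(delta))
  Ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(Ra_kJ = Ra * 1000, N = 24 / pi * ws)
}

# Brute-force Mann-Kendall oracles (explicit double loops).
mk_oracle_S <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i])
    }
  }
  S
}

mk_oracle_sigma <- function(x, tie_adjust = TRUE) {
  n <- length(x)
  v <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_adjust) {
    for (tk in table(x)) {
      if (tk > 1) v <- v - tk * (tk - 1) * (2 * tk + 5) / 18
    }
  }
  sqrt(v)
}

sen_oracle <- function(y, t = seq_along(y)) {
  sl <- c()
  n <- length(y)
  for (k in 1:(n - 1)) {
    for (j in (k + 1):n) {
      if (t[j] != t[k]) sl <- c(sl, (y[j] - y[k]) / (t[j] - t[k]))
    }
  }
  sl <- sort(sl)
  N <- length(sl)
  if (N %% 2 == 1) sl[(N + 1) / 2] else (sl[N / 2] + sl[N / 2 + 1]) / 2
}

# brute-force phenology oracle: first day whose preceding-phase heat sum
# (half-open interval) reaches the threshold
phen_oracle <- function(tave, doys, sow_doy, p) {
  heat <- pmax(tave, 0)
  cum <- 0; phase <- 1
  thresholds <- c(p$TSUM_em, p$TSUM1, p$TSUM2)
  dates <- c(NA, NA, NA)
  for (i in seq_along(doys)) {
    if (doys[i] < sow_doy) next
    while (phase <= 3 && cum >= thresholds[phase]) {
      dates[phase] <- doys[i]
      cum <- 0
      phase <- phase + 1
    }
    if (phase > 3) break
    cum <- cum + heat[i]
  }
  list(emergence = dates[1], anthesis = dates[2], maturity = dates[3])
}
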