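#' @title Daily-timestep potential-production crop simulator
#' @description Internal state initialisation for the crop engine.
#' @keywords internal
new_crop_state <- function(params) {
  fr0 <- afgen(params$FRTB, 0)
  shoot <- (1 - fr0) * params$TDWI
  wlv <- afgen(params$FLTB, 0) * shoot
  state <- list(
    stage = "pre_emergence",   # pre_emergence -> vegetative -> reproductive -> mature
    cum_em = 0, cum1 = 0, cum2 = 0,
    DVS = 0,
    WRT = fr0 * params$TDWI,
    WLV = wlv,
    WST = afgen(params$FSTB, 0) * shoot,
    WSO = afgen(params$FOTB, 0) * shoot,
    LAI = params$SLA * wlv,
    LV = wlv, LVAGE = 0,       # leaf cohorts: weights and physiological ages
    emerged_today = FALSE, anthesis_today = FALSE
  )
  state
}

#' Advance crop phenology by one day
#'
#' Thermal-time phenology with base temperature 0 degC for every phase.
#' Phase transitions are checked against the accumulated sums *before*
#' today's temperature is added, so phase intervals are half-open
#' \[start, end): the transition day's heat counts toward the new phase
#' exactly once. Development stage `DVS` runs 0 (emergence) to 1
#' (anthesis) to 2 (maturity).
#'
#' @param state Crop state list (see [run_potential()]).
#' @param Tave Daily mean temperature, degC.
#' @param params A [crop_params()] object.
#' @return Updated state; fields `emerged_today` / `anthesis_today` flag
#'   transitions that fired at the start of this day.
#' @export
phenology_step <- function(state, Tave, params) {
  if (state$stage == "mature") stop("phenology_step on a mature crop", call. = FALSE)
  state$emerged_today <- state$anthesis_today <- FALSE

  # start-of-day transitions against yesterday's accumulated sums
  if (state$stage == "pre_emergence" && state$cum_em >= params$TSUM_em) {
    state$stage <- "vegetative"
    state$emerged_today <- TRUE
  }
  if (state$stage == "vegetative" && state$cum1 >= params$TSUM1) {
    state$stage <- "reproductive"
    state$anthesis_today <- TRUE
  }
  if (state$stage == "reproductive" && state$cum2 >= params$TSUM2) {
    state$stage <- "mature"
    state$DVS <- 2
    return(state)
  }

  dtsum <- max(Tave - params$TBASE, 0)
  if (state$stage == "pre_emergence") {
    state$cum_em <- state$cum_em + dtsum
  } else if (state$stage == "vegetative") {
    state$cum1 <- state$cum1 + dtsum
  } else {
    state$cum2 <- state$cum2 + dtsum
  }
  state$DVS <- if (state$stage == "reproductive") {
    1 + min(state$cum2 / params$TSUM2, 1)
  } else {
    min(state$cum1 / params$TSUM1, 1)
  }
  state
}

# 3-point Gauss-Legendre abscissae/weights on [0, 1]
.gauss_x <- c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15))
.gauss_w <- c(5, 8, 5) / 18

#' Daily gross canopy assimilation
#'
#' Canopy gross photosynthesis for one day, integrated with three-point
#' Gaussian quadrature over canopy depth and over the daylight period.
#' Incident photosynthetically active radiation is taken as half of
#' global radiation. When station latitude and day of year are supplied,
#' the full WOFOST canopy scheme is used: incoming radiation is
#' distributed over the day with the solar-elevation profile, split into
#' diffuse and direct components from the atmospheric transmission, and
#' absorbed separately by sunlit and shaded leaf fractions, with canopy
#' scattering and reflection. Without solar geometry a simplified
#' homogeneous profile is used (cosine diurnal course, purely diffuse
#' extinction with coefficient `KDIF`). In both cases the leaf response
#' is the negative-exponential light-response curve with initial slope
#' `EFF` saturating at `AMAX`, and gross CO2 uptake is converted to
#' carbohydrate (CH2O) by the molar ratio 30/44.
#'
#' @param Ra Daily global radiation, kJ/m2/day.
#' @param N Daylength, hours.
#' @param LAI Leaf area index, ha/ha.
#' @param params A [crop_params()] object (uses `AMAX`, `EFF`, `KDIF` and
#'   the `AMAX_DVS` / `TMPFTB` modifier tables).
#' @param dvs Development stage; when supplied, the leaf photosynthetic
#'   capacity is scaled by the `AMAX_DVS` table (capacity declines towards
#'   maturity). `NULL` means no scaling.
#' @param Tday Mean daytime temperature, degC; when supplied, capacity is
#'   scaled by the `TMPFTB` response. `NULL` means no scaling.
#' @param lat,doy Station latitude (deg) and day of year enabling the
#'   full sunlit/shaded canopy scheme; both `NULL` selects the simplified
#'   profile.
#' @param n_gauss Number of quadrature points per dimension (3 = the
#'   production setting; larger values are used by reference integrations).
#' @return Gross assimilation, kg CH2O/ha/day. Zero when `LAI` or `Ra` is
#'   zero; bounded above by `AMAX * LAI * N * 30/44`.
#' @export
daily_gross_assimilation <- function(Ra, N, LAI, params, dvs = NULL,
                                     Tday = NULL, lat = NULL, doy = NULL,
                                     n_gauss = 3) {
  stopifnot(Ra >= 0, LAI >= 0, N >= 0)
  if (Ra == 0 || LAI == 0 || N == 0) return(0)

  amax <- params$AMAX
  if (!is.null(dvs)) amax <- amax * afgen(params$AMAX_DVS, dvs)
  if (!is.null(Tday)) amax <- amax * afgen(params$TMPFTB, Tday)
  if (amax <= 0) return(0)

  if (n_gauss == 3) {
    gx <- .gauss_x; gw <- .gauss_w
  } else {
    # composite midpoint rule for reference integrations
    gx <- (seq_len(n_gauss) - 0.5) / n_gauss
    gw <- rep(1 / n_gauss, n_gauss)
  }

  par_day <- 0.5 * Ra * 1000                      # J/m2/day, PAR fraction 0.5
  eff <- params$EFF; kdif <- params$KDIF

  if (!is.null(lat) && !is.null(doy)) {
    # --- full scheme: solar geometry, diffuse/direct, sunlit/shaded ---
    phi <- lat * pi / 180
    delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
    sinld <- sin(phi) * sin(delta)
    cosld <- cos(phi) * cos(delta)
    aob <- max(-1, min(1, sinld / cosld))
    # day-integral of sinb*(1 + 0.4 sinb), seconds
    dsinbe <- 3600 * (N * (sinld + 0.4 * (sinld^2 + cosld^2 * 0.5)) +
                        12 * cosld * (2 + 3 * 0.4 * sinld) *
                          sqrt(1 - aob^2) / pi)
    sc <- 1370 * (1 + 0.033 * cos(2 * pi * doy / 365))  # W/m2
    scv <- 0.2                                          # leaf scattering (PAR)
    refh <- (1 - sqrt(1 - scv)) / (1 + sqrt(1 - scv))

    hour_rate <- function(xh) {
      hour <- 12 + 0.5 * N * xh
      sinb <- max(1e-6, sinld + cosld * cos(2 * pi * (hour + 12) / 24))
      part <- par_day * sinb * (1 + 0.4 * sinb) / dsinbe  # J/m2/s PAR
      atmtr <- part / (0.5 * sc * sinb)
      frdif <- if (atmtr <= 0.07) 1
        else if (atmtr <= 0.35) 1 - 2.3 * (atmtr - 0.07)^2
        else max(0.23, 1.33 - 1.46 * atmtr)
      pardif <- frdif * part
      pardir <- part - pardif
      refs <- refh * 2 / (1 + 1.6 * sinb)
      kdirbl <- (0.5 / sinb) * kdif / (0.8 * sqrt(1 - scv))
      kdirt <- kdirbl * sqrt(1 - scv)
      laic <- LAI * gx
      visdf <- (1 - refs) * pardif * kdif * exp(-kdif * laic)
      vist <- (1 - refs) * pardir * kdirt * exp(-kdirt * laic)
      visd <- (1 - scv) * pardir * kdirbl * exp(-kdirbl * laic)
      visshd <- pmax(0, visdf + vist - visd)      # absorbed by shaded leaves
      fgrsh <- amax * (1 - exp(-visshd * eff / amax))
      vispp <- (1 - scv) * pardir / sinb          # on perpendicular leaves
      fgrsun <- if (vispp <= 1e-12) fgrsh else {
        amax * (1 - (amax - fgrsh) *
                  (1 - exp(-vispp * eff / amax)) / (eff * vispp))
      }
      fslla <- exp(-kdirbl * laic)                # sunlit leaf fraction
      LAI * sum(gw * (fslla * fgrsun + (1 - fslla) * fgrsh))
    }
    rates <- vapply(gx, hour_rate, numeric(1))
  } else {
    # --- simplified profile: cosine diurnal course, diffuse extinction ---
    i_noon <- par_day * pi / (2 * N * 3600)       # J/m2/s at solar noon
    canopy_rate <- function(i0) {
      il <- kdif * i0 * exp(-kdif * LAI * gx)
      LAI * sum(gw * amax * (1 - exp(-eff * il / amax)))
    }
    rates <- vapply(gx, function(f) canopy_rate(i_noon * cos(pi * f / 2)),
                    numeric(1))
  }
  dtga_co2 <- N * sum(gw * rates)                  # kg CO2/ha/day
  dtga_co2 * 30 / 44
}

#' Maintenance respiration
#'
#' Organ-weighted maintenance costs with a Q10 temperature response
#' relative to the 25 degC reference:
#' `RM = (RML*WLV + RMS*WST + RMO*WSO + RMR*WRT) * Q10^((Tave - 25)/10)`,
#' capped at the day's gross assimilation so that maintenance can never
#' turn daily growth negative.
#'
#' @param state Crop state (organ weights `WLV`, `WST`, `WSO`, `WRT`).
#' @param Tave Daily mean temperature, degC.
#' @param params A [crop_params()] object.
#' @param gross Daily gross assimilation used as the cap (default `Inf`,
#'   i.e. uncapped).
#' @return Maintenance respiration, kg CH2O/ha/day.
#' @export
maintenance_respiration <- function(state, Tave, params, gross = Inf) {
  rm0 <- params$RML * state$WLV + params$RMS * state$WST +
    params$RMO * state$WSO + params$RMR * state$WRT
  min(rm0 * params$Q10^((Tave - params$TREF) / 10), gross)
}

#' Partition net assimilate into organ growth
#'
#' Splits the day's net assimilate (gross minus maintenance) between root
#' and shoot by the DVS-indexed root fraction, distributes the shoot share
#' over leaves, stems and storage organs, and converts carbohydrate to
#' structural dry matter with organ-specific efficiencies. The residual
#' `net * (1 - sum(CV * fraction))` is the growth-respiration loss.
#'
#' @param net Net assimilate, kg CH2O/ha/day (non-negative).
#' @param state Crop state (uses `DVS`).
#' @param params A [crop_params()] object.
#' @return List with organ increments `dWRT, dWLV, dWST, dWSO` (kg DM/ha)
#'   and `conversion_loss` (kg CH2O/ha).
#' @export
partition_and_grow <- function(net, state, params) {
  stopifnot(net >= 0)
  fr <- afgen(params$FRTB, state$DVS)
  fl <- afgen(params$FLTB, state$DVS)
  fs <- afgen(params$FSTB, state$DVS)
  fo <- afgen(params$FOTB, state$DVS)
  if (abs(fl + fs + fo - 1) > 1e-9) {
    stop("shoot partitioning fractions do not sum to 1", call. = FALSE)
  }
  d <- list(
    dWRT = params$CVR * fr * net,
    dWLV = params$CVL * (1 - fr) * fl * net,
    dWST = params$CVS * (1 - fr) * fs * net,
    dWSO = params$CVO * (1 - fr) * fo * net
  )
  d$conversion_loss <- net - (d$dWRT + d$dWLV + d$dWST + d$dWSO)
  d
}

#' Leaf cohort dynamics
#'
#' Ages every leaf cohort by the physiological increment
#' `max(Tave - TBASE_AGE, 0) / (35 - TBASE_AGE)` (one unit per day at
#' 35 degC), removes cohorts whose physiological age has reached `SPAN`,
#' and appends today's new leaf growth as a fresh cohort. Leaf area grows
#' with specific leaf area `SLA`; during the juvenile phase (LAI below
#' `LAI_EXP_MAX`, before anthesis) the area increment is additionally
#' capped by the exponential bound `LAI * (exp(RGRLAI * dTeff) - 1)`.
#'
#' @param state Crop state.
#' @param Tave Daily mean temperature, degC.
#' @param params A [crop_params()] object.
#' @param new_leaf_weight Today's leaf dry-matter increment, kg/ha.
#' @return Updated state plus field `senesced_today` (kg/ha leaf weight
#'   lost to senescence).
#' @export
leaf_dynamics <- function(state, Tave, params, new_leaf_weight = 0) {
  dteff <- max(Tave - params$TBASE_AGE, 0)
  fysage <- dteff / (35 - params$TBASE_AGE)
  state$LVAGE <- state$LVAGE + fysage

  dead <- state$LVAGE >= params$SPAN
  senesced <- sum(state$LV[dead])
  if (any(dead)) {
    state$LV <- state$LV[!dead]
    state$LVAGE <- state$LVAGE[!dead]
  }

  gla <- params$SLA * new_leaf_weight
  if (state$DVS < 1 && state$LAI < params$LAI_EXP_MAX && state$LAI > 0) {
    gla <- min(gla, state$LAI * (exp(params$RGRLAI * dteff) - 1))
  }
  if (new_leaf_weight > 0) {
    state$LV <- c(state$LV, new_leaf_weight)
    state$LVAGE <- c(state$LVAGE, 0)
  }
  state$WLV <- state$WLV + new_leaf_weight - senesced
  state$LAI <- max(state$LAI + gla - params$SLA * senesced, 0)
  state$senesced_today <- senesced
  state
}

#' Run a potential-production simulation for one station-year
#'
#' Integrates phenology, canopy assimilation, maintenance respiration,
#' dry-matter partitioning and leaf dynamics on a daily time step from the
#' sowing date until maturity (development stage 2) or the end of the
#' available season, whichever comes first. Production is limited only by
#' radiation, temperature and crop traits: water and nutrients are assumed
#' non-limiting.
#'
#' @param weather Data.frame of derived daily weather for one station-year
#'   ([derive_daily()] output or equivalent) with columns `doy, tave, Ra,
#'   N`; rows must be consecutive days covering the sowing date onward.
#' @param params A [crop_params()] object.
#' @param sowing_doy Integer day of year of sowing.
#' @param latitude Station latitude (deg); when supplied the full
#'   sunlit/shaded canopy scheme is used (see
#'   [daily_gross_assimilation()]).
#' @param season_end_doy Last day simulated if maturity is not reached
#'   (default 304, i.e. 31 October in non-leap years).
#' @param save_trajectory If `TRUE`, attach the daily state trajectory.
#' @return A list of class `simulation_result`: `sowing_doy`,
#'   `emergence_doy`, `anthesis_doy`, `maturity_doy` (NA when not
#'   reached), `duration` (emergence to maturity, days),
#'   `potential_yield` (storage-organ weight, kg/ha),
#'   `termination_reason` (`"maturity"` or `"season_end"`), final organ
#'   weights, and a carbon `balance` list (gross, maintenance, conversion
#'   losses, senesced, closure error).
#' @export
run_potential <- function(weather, params, sowing_doy, latitude = NULL,
                          season_end_doy = 304, save_trajectory = FALSE) {
  w <- weather[order(weather$doy), , drop = FALSE]
  sel <- w$doy >= sowing_doy & w$doy <= season_end_doy
  w <- w[sel, , drop = FALSE]
  if (nrow(w) == 0 || w$doy[1] != sowing_doy) {
    stop("weather does not cover the sowing date (doy ", sowing_doy, ")",
         call. = FALSE)
  }
  gaps <- which(diff(w$doy) != 1)
  if (length(gaps) > 0) {
    stop("weather gap: missing doy ", w$doy[gaps[1]] + 1, call. = FALSE)
  }

  state <- new_crop_state(params)
  tdwi0 <- state$WRT + state$WLV + state$WST + state$WSO
  acc <- list(gross = 0, maint = 0, conv = 0, senesced = 0)
  emergence_doy <- anthesis_doy <- maturity_doy <- NA_integer_
  traj <- if (save_trajectory) vector("list", nrow(w)) else NULL

  for (i in seq_len(nrow(w))) {
    day <- w[i, ]
    state <- phenology_step(state, day$tave, params)
    if (state$emerged_today) emergence_doy <- day$doy
    if (state$anthesis_today) anthesis_doy <- day$doy
    if (state$stage == "mature") {
      maturity_doy <- day$doy
      break
    }
    if (state$stage != "pre_emergence") {
      # daytime temperature approximated from the daily extremes when present
      tday <- if (!is.null(day$tmax) && !is.null(day$tmin)) {
        day$tave + 0.25 * (day$tmax - day$tmin)
      } else {
        day$tave
      }
      gross <- daily_gross_assimilation(day$Ra, day$N, state$LAI, params,
                                        dvs = state$DVS, Tday = tday,
                                        lat = latitude, doy = day$doy)
      maint <- maintenance_respiration(state, day$tave, params, gross = gross)
      grow <- partition_and_grow(gross - maint, state, params)
      state$WRT <- state$WRT + grow$dWRT
      state$WST <- state$WST + grow$dWST
      state$WSO <- state$WSO + grow$dWSO
      state <- leaf_dynamics(state, day$tave, params,
                             new_leaf_weight = grow$dWLV)
      acc$gross <- acc$gross + gross
      acc$maint <- acc$maint + maint
      acc$conv <- acc$conv + grow$conversion_loss
      acc$senesced <- acc$senesced + state$senesced_today
    }
    if (save_trajectory) {
      traj[[i]] <- data.frame(doy = day$doy, stage = state$stage,
                              DVS = state$DVS, LAI = state$LAI,
                              WRT = state$WRT, WLV = state$WLV,
                              WST = state$WST, WSO = state$WSO)
    }
  }

  biomass <- state$WRT + state$WLV + state$WST + state$WSO
  closure <- (acc$gross - acc$maint - acc$conv - acc$senesced) -
    (biomass - tdwi0)
  res <- list(
    variety = params$variety,
    sowing_doy = as.integer(sowing_doy),
    emergence_doy = emergence_doy,
    anthesis_doy = anthesis_doy,
    maturity_doy = maturity_doy,
    duration = if (!is.na(maturity_doy) && !is.na(emergence_doy)) {
      maturity_doy - emergence_doy
    } else NA_integer_,
    potential_yield = state$WSO,
    WRT = state$WRT, WLV = state$WLV, WST = state$WST, WSO = state$WSO,
    LAI = state$LAI,
    termination_reason = if (!is.na(maturity_doy)) "maturity" else "season_end",
    balance = list(gross = acc$gross, maintenance = acc$maint,
                   conversion_loss = acc$conv, senesced = acc$senesced,
                   closure_error = closure,
                   relative_closure = if (acc$gross > 0) {
                     abs(closure) / acc$gross
                   } else 0)
  )
  if (save_trajectory) {
    res$trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  }
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "potential-production run (%s): sowing doy %d, emergence %s, anthesis %s, maturity %s\n",
    x$variety, x$sowing_doy,
    ifelse(is.na(x$emergence_doy), "-", x$emergence_doy),
    ifelse(is.na(x$anthesis_doy), "-", x$anthesis_doy),
    ifelse(is.na(x$maturity_doy), "-", x$maturity_doy)))
  cat(sprintf("  potential yield %.0f kg/ha (%s)\n",
              x$potential_yield, x$termination_reason))
  invisible(x)
}
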