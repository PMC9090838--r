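#' Crop parameter set for a highland-barley variety
#'
#' Returns the full parameter list driving the potential-production
#' simulator. Thermal-time requirements (base 0 degC) are variety-specific:
#'
#' | variety       | sowing-emergence | emergence-anthesis | anthesis-maturity |
#' |---------------|------------------|--------------------|-------------------|
#' | Chaiqing-1    | 100              | 650                | 850               |
#' | Zangqing-2000 | 100              | 700                | 950               |
#' | Diqing-1      | 100              | 800                | 1050              |
#'
#' Physiology follows the standard WOFOST potential-production scheme
#' instantiated for spring barley: maximum leaf CO2 assimilation
#' `AMAX = 35` kg CO2/ha/h, leaf life span `SPAN = 25` d at 35 degC,
#' `RGRLAI = 0.0075` ha/ha/d, maintenance coefficients
#' `RML/RMS/RMO/RMR = 0.03/0.015/0.01/0.01` kg CH2O/kg/d with `Q10 = 2`
#' (reference 25 degC), initial light-use efficiency
#' `EFF = 0.45` kg CO2/ha/h per J/m2/s, diffuse extinction `KDIF = 0.60`,
#' assimilate-conversion efficiencies `CVL/CVO/CVR/CVS =
#' 0.685/0.709/0.694/0.662` kg DM/kg CH2O, specific leaf area
#' `SLA = 0.0022` ha/kg, initial total dry weight `TDWI = 75` kg/ha, and
#' development-stage-indexed dry-matter partitioning (see `FRTB`, `FLTB`,
#' `FSTB`, `FOTB` in the returned list). Shoot fractions sum to one at
#' every development stage.
#'
#' @param variety One of `"Chaiqing-1"`, `"Zangqing-2000"`, `"Diqing-1"`.
#' @param ... Named overrides for any parameter (e.g. `AMAX = 0` for a
#'   no-photosynthesis control run).
#' @return A list of class `crop_params`.
#' @export
crop_params <- function(variety = c("Chaiqing-1", "Zangqing-2000", "Diqing-1"),
                        ...) {
  variety <- match.arg(variety)
  tsums <- switch(variety,
    "Chaiqing-1"    = c(em = 100, t1 = 650, t2 = 850),
    "Zangqing-2000" = c(em = 100, t1 = 700, t2 = 950),
    "Diqing-1"      = c(em = 100, t1 = 800, t2 = 1050)
  )
  p <- list(
    variety = variety,
    TSUM_em = unname(tsums["em"]),
    TSUM1   = unname(tsums["t1"]),
    TSUM2   = unname(tsums["t2"]),
    TBASE   = 0,        # degC, thermal-time base for all phases
    AMAX    = 35.0,     # kg CO2 / ha / h (plateau value)
    # relative AMAX by development stage: full capacity through grain set,
    # strong decline towards maturity (spring-barley convention)
    AMAX_DVS = cbind(dvs = c(0, 1.0, 1.3, 2.0),
                     f   = c(1, 1, 1, 0.128)),
    # relative AMAX vs daytime temperature (degC)
    TMPFTB = cbind(t = c(-10, 0, 10, 15, 25, 35),
                   f = c(0, 0.01, 0.60, 1.0, 1.0, 0)),
    EFF     = 0.45,     # kg CO2 / ha / h per J / m2 / s
    KDIF    = 0.60,
    SPAN    = 25.0,     # d (physiological, at 35 degC)
    TBASE_AGE = 0,      # degC, base for leaf physiological ageing
    RGRLAI  = 0.0075,   # ha / ha / d
    PERDL   = 0.02,     # kg / kg / d (water-stress death; inactive here)
    SLA     = 0.0022,   # ha / kg
    TDWI    = 75,       # kg / ha
    LAI_EXP_MAX = 0.75, # LAI ceiling of the exponential juvenile phase
    RML = 0.03, RMS = 0.015, RMO = 0.01, RMR = 0.01,  # kg CH2O / kg / d
    Q10 = 2.0,
    TREF = 25,          # degC, maintenance-respiration reference
    CVL = 0.685, CVO = 0.709, CVR = 0.694, CVS = 0.662,
    # root fraction of total dry-matter increase, by DVS
    FRTB = cbind(dvs = c(0, 0.4, 1.0, 2.0),
                 fr  = c(0.50, 0.25, 0.00, 0.00)),
    # shoot partitioning (fractions of shoot increase), shared DVS nodes so
    # linear interpolation preserves the sum-to-one constraint
    FLTB = cbind(dvs = c(0, 0.5, 0.8, 1.0, 1.3, 2.0),
                 f   = c(0.65, 0.50, 0.15, 0.00, 0.00, 0.00)),
    FSTB = cbind(dvs = c(0, 0.5, 0.8, 1.0, 1.3, 2.0),
                 f   = c(0.35, 0.50, 0.75, 0.60, 0.00, 0.00)),
    FOTB = cbind(dvs = c(0, 0.5, 0.8, 1.0, 1.3, 2.0),
                 f   = c(0.00, 0.00, 0.10, 0.40, 1.00, 1.00))
  )
  over <- list(...)
  if (length(over) > 0) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown) > 0) {
      stop("unknown crop parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  stopifnot(p$TSUM_em > 0, p$TSUM1 > 0, p$TSUM2 > 0)
  check_partition_tables(p)
  class(p) <- "crop_params"
  p
}

#' Linear interpolation in a WOFOST-style (x, y) table
#' @param tb Two-column matrix (x, y); x strictly increasing.
#' @param x Query points; clamped to the table range.
#' @return Interpolated values.
#' @keywords internal
afgen <- function(tb, x) {
  stats::approx(tb[, 1], tb[, 2], xout = pmin(pmax(x, tb[1, 1]),
                                              tb[nrow(tb), 1]))$y
}

# shoot fractions must sum to 1 at every DVS node (and hence, by shared
# nodes + linearity, everywhere)
check_partition_tables <- function(p) {
  dvs <- p$FLTB[, 1]
  if (!identical(dvs, p$FSTB[, 1]) || !identical(dvs, p$FOTB[, 1])) {
    stop("partitioning tables must share DVS nodes", call. = FALSE)
  }
  s <- p$FLTB[, 2] + p$FSTB[, 2] + p$FOTB[, 2]
  if (any(abs(s - 1) > 1e-9)) {
    stop("shoot partitioning fractions must sum to 1 at every DVS", call. = FALSE)
  }
  if (any(p$FRTB[, 2] < 0 | p$FRTB[, 2] > 1)) {
    stop("root fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default sowing dates by variety
#'
#' Chaiqing-1 is sown 10 April, Zangqing-2000 20 April and Diqing-1
#' 30 April; dates are held fixed across years so that simulated
#' inter-annual yield variation reflects weather alone.
#'
#' @param variety Variety name.
#' @return Sowing day as `c(month, day)`.
#' @export
default_sowing_date <- function(variety) {
  switch(variety,
    "Chaiqing-1"    = c(4L, 10L),
    "Zangqing-2000" = c(4L, 20L),
    "Diqing-1"      = c(4L, 30L),
    stop("unknown variety: ", variety, call. = FALSE)
  )
}
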