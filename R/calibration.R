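#' Derive thermal-time requirements from observed phenology
#'
#' Sums daily mean temperature above the 0 degC base over each observed
#' phase. Phase intervals are half-open `[phase_start, phase_end)`: the
#' temperature of a phase's first day counts toward that phase and a
#' boundary day is never counted twice. Phases whose bounding dates are
#' missing are returned as `NA` and flagged.
#'
#' @param tave_series Data.frame with columns `date` (Date) and `tave`
#'   (degC) covering sowing through maturity.
#' @param phenology List or one-row data.frame with `sown_date`,
#'   `emergence_date`, `anthesis_date` (optional, may be `NA`),
#'   `maturity_date` (Dates).
#' @param round50 If `TRUE`, round each sum to the nearest 50 degC day
#'   (the convention used for parameter files).
#' @return List with `TSUM_em`, `TSUM1`, `TSUM2` (degC day; `NA` when a
#'   phase is missing; `TSUM1` spans emergence to maturity when anthesis
#'   is unobserved and is then reported in `TSUM_em_to_maturity` instead)
#'   and `flags`, a character vector naming skipped phases.
#' @export
derive_tsum <- function(tave_series, phenology, round50 = FALSE) {
  ph <- as.list(phenology)
  s <- tave_series[order(tave_series$date), ]
  eat_between <- function(from, to) {
    # half-open [from, to)
    if (is.na(from) || is.na(to)) return(NA_real_)
    sel <- s$date >= from & s$date < to
    if (!any(sel) && from < to) {
      stop("temperature series does not cover ", from, " to ", to, call. = FALSE)
    }
    sum(pmax(s$tave[sel], 0))
  }
  anth <- if (!is.null(ph$anthesis_date)) ph$anthesis_date else NA
  out <- list(
    TSUM_em = eat_between(ph$sown_date, ph$emergence_date),
    TSUM1 = eat_between(ph$emergence_date, anth),
    TSUM2 = eat_between(anth, ph$maturity_date),
    TSUM_em_to_maturity = eat_between(ph$emergence_date, ph$maturity_date)
  )
  flags <- character(0)
  if (is.na(out$TSUM_em)) flags <- c(flags, "sowing-emergence")
  if (is.na(out$TSUM1)) flags <- c(flags, "emergence-anthesis")
  if (is.na(out$TSUM2)) flags <- c(flags, "anthesis-maturity")
  if (round50) {
    out[1:4] <- lapply(out[1:4], function(v) {
      if (is.na(v)) v else round(v / 50) * 50
    })
  }
  out$flags <- flags
  out
}

#' Agreement metrics between observed and simulated values
#'
#' The five scores used to judge simulated yields and growing durations
#' against observations: Pearson correlation `r`, its square `R2`, root
#' mean square error `RMSE`, relative RMSE
#' `RRMSE = RMSE / mean(obs) * 100%`, and the percentage deviation
#' coefficient `PDC = sum(obs - sim) / sum(obs) * 100%`.
#'
#' @param observed,simulated Numeric vectors of equal length (n >= 2);
#'   `mean(observed)` must be nonzero.
#' @return A list of class `validation_report` with `r`, `R2`, `RMSE`,
#'   `RRMSE`, `PDC`, `n`. `r` (and `R2`) are `NA` when either vector has
#'   zero variance.
#' @export
validation_metrics <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least two paired values", call. = FALSE)
  if (mean(observed) == 0) stop("mean(observed) is zero; RRMSE undefined", call. = FALSE)
  r <- if (stats::sd(observed) == 0 || stats::sd(simulated) == 0) {
    NA_real_
  } else {
    stats::cor(observed, simulated)
  }
  rmse <- sqrt(mean((observed - simulated)^2))
  out <- list(
    r = r,
    R2 = r^2,
    RMSE = rmse,
    RRMSE = rmse / mean(observed) * 100,
    PDC = sum(observed - simulated) / sum(observed) * 100,
    n = n
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation on n = %d pairs:\n", x$n))
  cat(sprintf("  r = %.3f, R2 = %.3f, RMSE = %.3f, RRMSE = %.2f%%, PDC = %.2f%%\n",
              x$r, x$R2, x$RMSE, x$RRMSE, x$PDC))
  invisible(x)
}

#' Read a phenology/calibration record file
#'
#' Delimited text with columns `station_id, year, sown_date,
#' emergence_date, anthesis_date, maturity_date, observed_yield,
#' observed_duration` (dates ISO-8601, blanks allowed for unobserved
#' phases).
#'
#' @param path File path.
#' @return Data.frame with dates parsed.
#' @export
read_phenology <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in c("sown_date", "emergence_date", "anthesis_date", "maturity_date")) {
    if (col %in% names(x)) x[[col]] <- as.Date(x[[col]])
  }
  x
}
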