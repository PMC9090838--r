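#' First-difference an annual series
#'
#' `dx_t = x_t - x_{t-1}` between consecutive years. Gaps in the year
#' sequence split the series into runs; a difference is never taken
#' across a gap.
#'
#' @param value Numeric values.
#' @param year Corresponding years (default consecutive).
#' @return Data.frame with columns `year` (the later year of each pair)
#'   and `delta`; `(n - gaps - 1)` rows.
#' @export
first_difference <- function(value, year = seq_along(value)) {
  if (length(value) < 2) stop("need at least two values", call. = FALSE)
  o <- order(year)
  value <- value[o]; year <- year[o]
  consecutive <- diff(year) == 1
  data.frame(year = year[-1][consecutive],
             delta = diff(value)[consecutive])
}

#' Classify a station into a temperature zone
#'
#' Zones by annual accumulated temperature above 0 degC (degC day):
#' TZ-1 below 2000, TZ-2 \[2000, 2500), TZ-3 \[2500, 3000),
#' TZ-4 \[3000, 3500), TZ-5 at and above 3500. Intervals are closed on
#' the left so every positive input maps to exactly one zone.
#'
#' @param at0 Annual accumulated temperature above 0 degC; positive.
#' @return Character vector of zone ids (`"TZ-1"` ... `"TZ-5"`).
#' @export
classify_zone <- function(at0) {
  if (any(!is.finite(at0)) || any(at0 <= 0)) {
    stop("accumulated temperature must be positive", call. = FALSE)
  }
  breaks <- c(-Inf, 2000, 2500, 3000, 3500, Inf)
  paste0("TZ-", findInterval(at0, breaks[-1]) + 1)
}

#' Build first-difference yield-climate panels by temperature zone
#'
#' Joins the station-year yield table with the seasonal climate summaries,
#' first-differences yield and each climate factor within station (never
#' across year gaps), assigns every station to a temperature zone by its
#' long-term mean annual accumulated temperature above 0 degC, and pools
#' the station-year differences within each zone.
#'
#' @param yields Data.frame with `station_id, year, yield_kg_ha` (rows
#'   with `NA` yield, e.g. immature seasons, are dropped).
#' @param seasonal Data.frame of [seasonal_summary()] rows (columns
#'   `station_id, year, tave, tmax, tmin, tdr, EAT, RA, annual_AT0`).
#' @return Data.frame with columns `zone, station_id, year, dYp, dTave,
#'   dTmax, dTmin, dEAT, dTDR, dRA`.
#' @export
build_zone_panel <- function(yields, seasonal) {
  m <- merge(yields, seasonal, by = c("station_id", "year"))
  m <- m[!is.na(m$yield_kg_ha), , drop = FALSE]
  zones <- tapply(m$annual_AT0, m$station_id, mean)
  vars <- c(yield_kg_ha = "dYp", tave = "dTave", tmax = "dTmax",
            tmin = "dTmin", EAT = "dEAT", tdr = "dTDR", RA = "dRA")
  panels <- lapply(split(m, m$station_id), function(g) {
    g <- g[order(g$year), ]
    if (nrow(g) < 2) return(NULL)
    out <- NULL
    for (v in names(vars)) {
      fd <- first_difference(g[[v]], g$year)
      names(fd)[2] <- vars[[v]]
      out <- if (is.null(out)) fd else merge(out, fd, by = "year")
    }
    if (nrow(out) == 0) return(NULL)
    data.frame(zone = classify_zone(zones[[g$station_id[1]]]),
               station_id = g$station_id[1], out,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, panels[!vapply(panels, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Pearson correlations of climate differences with yield differences
#'
#' Correlates each first-differenced climate factor with the
#' first-differenced potential yield within a panel, with two-sided
#' t-based significance at the 0.1, 0.05 and 0.01 levels (markers `*`,
#' `**`, `***`).
#'
#' @param panel Data.frame with `dYp` and predictor columns (default the
#'   six climate factors).
#' @param predictors Character vector of predictor column names.
#' @return Data.frame with `predictor, r, p, significance_class, marker,
#'   n`; `r` is `NA` for zero-variance columns.
#' @export
pearson_matrix <- function(panel,
                           predictors = c("dTave", "dTmax", "dTmin",
                                          "dEAT", "dTDR", "dRA")) {
  if (nrow(panel) < 3) stop("need at least 3 panel rows", call. = FALSE)
  n <- nrow(panel)
  rows <- lapply(predictors, function(v) {
    x <- panel[[v]]; y <- panel$dYp
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(predictor = v, r = NA_real_, p = NA_real_,
                        significance_class = "undefined", marker = "",
                        n = n, stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    cls <- if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05"
           else if (p < 0.1) "p<0.1" else "n.s."
    marker <- c("p<0.01" = "***", "p<0.05" = "**", "p<0.1" = "*",
                "n.s." = "")[[cls]]
    data.frame(predictor = v, r = r, p = p, significance_class = cls,
               marker = marker, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise multiple linear regression of yield on climate differences
#'
#' Bidirectional p-value stepwise selection on ordinary least squares:
#' at each iteration the candidate with the smallest partial p-value
#' enters if `p <= p_enter`, then any included predictor with partial
#' `p >= p_remove` is dropped (largest first); iteration stops at a fixed
#' point. Collinear candidates that do not add rank are never entered.
#'
#' @param panel Data.frame with response `dYp` and predictor columns.
#' @param predictors Candidate predictor names.
#' @param p_enter,p_remove Entry / removal thresholds (defaults 0.05 /
#'   0.10).
#' @return List of class `stepwise_fit`: `selected` (character),
#'   `coefficients` (named, incl. intercept), `F`, `p`, `R2`, `RMSE`
#'   (residual, kg/ha), `n`, `model` (the `lm` fit), `equation`
#'   (display string). With no surviving predictor an intercept-only
#'   result is returned with `selected = character(0)`.
#' @export
stepwise_mlr <- function(panel,
                         predictors = c("dTave", "dTmax", "dTmin",
                                        "dEAT", "dTDR", "dRA"),
                         p_enter = 0.05, p_remove = 0.10) {
  if (nrow(panel) < 10) stop("need at least 10 panel rows", call. = FALSE)
  stopifnot(all(c("dYp", predictors) %in% names(panel)))

  selected <- character(0)
  partial_p <- function(vars) {
    # partial p-values of each term in lm(dYp ~ vars)
    f <- stats::as.formula(paste("dYp ~", paste(vars, collapse = " + ")))
    fit <- stats::lm(f, data = panel)
    cf <- summary(fit)$coefficients
    p <- cf[, "Pr(>|t|)"]
    p[setdiff(rownames(cf), "(Intercept)")]
  }

  repeat {
    changed <- FALSE
    # forward: best candidate by partial p in the augmented model
    candidates <- setdiff(predictors, selected)
    if (length(candidates) > 0) {
      pvals <- vapply(candidates, function(v) {
        fit <- stats::lm(stats::as.formula(
          paste("dYp ~", paste(c(selected, v), collapse = " + "))),
          data = panel)
        cf <- summary(fit)$coefficients
        if (!(v %in% rownames(cf))) return(NA_real_)  # rank-deficient: skip
        cf[v, "Pr(>|t|)"]
      }, numeric(1))
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) > 0 && min(pvals) <= p_enter) {
        selected <- c(selected, names(pvals)[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward: drop worst included predictor
    if (length(selected) > 0) {
      pp <- partial_p(selected)
      while (length(pp) > 0 && max(pp) >= p_remove) {
        selected <- setdiff(selected, names(pp)[which.max(pp)])
        changed <- TRUE
        if (length(selected) == 0) break
        pp <- partial_p(selected)
      }
    }
    if (!changed) break
  }

  rhs <- if (length(selected) > 0) paste(selected, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste("dYp ~", rhs)), data = panel)
  sm <- summary(fit)
  fstat <- if (length(selected) > 0) unname(sm$fstatistic["value"]) else NA_real_
  pval <- if (length(selected) > 0) {
    stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
              sm$fstatistic["dendf"], lower.tail = FALSE)
  } else NA_real_
  cf <- stats::coef(fit)
  eq <- if (length(selected) > 0) {
    terms <- sprintf("%.2f*%s", cf[selected], selected)
    sprintf("dYp = %s %+.2f", paste(terms, collapse = " + "), cf[["(Intercept)"]])
  } else {
    sprintf("dYp = %.2f (intercept only)", cf[["(Intercept)"]])
  }
  structure(list(selected = selected, coefficients = cf,
                 F = fstat, p = unname(pval),
                 R2 = if (length(selected) > 0) sm$r.squared else 0,
                 RMSE = sqrt(mean(stats::residuals(fit)^2)),
                 n = nrow(panel), model = fit, equation = eq),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(x$equation, "\n")
  if (length(x$selected) > 0) {
    cat(sprintf("  F = %.2f, p = %.3g, R2 = %.3f, RMSE = %.1f, n = %d\n",
                x$F, x$p, x$R2, x$RMSE, x$n))
  } else {
    cat("  no predictor entered the model\n")
  }
  invisible(x)
}

#' Per-zone attribution report
#'
#' Runs [pearson_matrix()] and [stepwise_mlr()] on each zone's pooled
#' panel.
#'
#' @param panel Output of [build_zone_panel()].
#' @param min_rows Zones with fewer pooled rows are skipped (default 10).
#' @param ... Passed to [stepwise_mlr()].
#' @return List with `correlations` (data.frame, all zones stacked) and
#'   `regressions` (named list of `stepwise_fit` per zone, plus `"ALL"`
#'   for the pooled panel).
#' @export
attribute_zones <- function(panel, min_rows = 10, ...) {
  zones <- split(panel, panel$zone)
  zones[["ALL"]] <- panel
  cors <- lapply(names(zones), function(z) {
    if (nrow(zones[[z]]) < 3) return(NULL)
    cbind(zone = z, pearson_matrix(zones[[z]]))
  })
  regs <- lapply(zones, function(g) {
    if (nrow(g) < min_rows) return(NULL)
    stepwise_mlr(g, ...)
  })
  list(correlations = do.call(rbind, cors[!vapply(cors, is.null, logical(1))]),
       regressions = regs[!vapply(regs, is.null, logical(1))])
}
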