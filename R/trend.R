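#' Mann-Kendall S statistic
#'
#' `S = sum_{i<j} sgn(x_j - x_i)` over all ordered pairs of an annual
#' series.
#'
#' @param x Numeric vector in time order (n >= 2).
#' @return Integer S with `|S| <= n(n-1)/2`.
#' @export
mk_statistic <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two values", call. = FALSE)
  d <- sign(outer(x, x, "-"))
  # sum of sgn(x_j - x_i) over j > i is the lower triangle of d
  sum(d[lower.tri(d)])
}

#' Mann-Kendall trend test
#'
#' Two-sided Mann-Kendall test with the continuity-corrected normal
#' approximation `Z = (S -/+ 1)/sigma` and significance classes at the
#' 0.1, 0.05 and 0.01 levels (the MAKESENS convention; marker symbols
#' `+`, `x`, `*` respectively, `-` for no significant trend).
#'
#' Two variance modes are available: `"tie_adjusted"` (default) subtracts
#' the standard tie term `sum(t_k (t_k - 1)(2 t_k + 5))/18`;
#' `"as_printed"` uses the uncorrected `n(n-1)(2n+5)/18` regardless of
#' ties.
#'
#' @param x Numeric vector in time order; n >= 4.
#' @param variance `"tie_adjusted"` or `"as_printed"`.
#' @return List of class `trend_test` with `S`, `sigma`, `Z`, `p`
#'   (two-sided), `significance_class` (one of `"p<0.01"`, `"p<0.05"`,
#'   `"p<0.1"`, `"n.s."`), `marker`, `n`.
#' @export
mk_test <- function(x, variance = c("tie_adjusted", "as_printed")) {
  variance <- match.arg(variance)
  n <- length(x)
  if (n < 4) {
    stop("Mann-Kendall test needs at least 4 values (normal approximation); got ",
         n, call. = FALSE)
  }
  S <- mk_statistic(x)
  var_s <- n * (n - 1) * (2 * n + 5) / 18
  if (variance == "tie_adjusted") {
    t_k <- table(x)
    t_k <- t_k[t_k > 1]
    if (length(t_k) > 0) {
      var_s <- var_s - sum(t_k * (t_k - 1) * (2 * t_k + 5)) / 18
    }
  }
  sigma <- sqrt(var_s)
  Z <- if (S > 0) (S - 1) / sigma else if (S < 0) (S + 1) / sigma else 0
  p <- 2 * stats::pnorm(-abs(Z))
  cls <- if (abs(Z) >= stats::qnorm(0.995)) "p<0.01"
         else if (abs(Z) >= stats::qnorm(0.975)) "p<0.05"
         else if (abs(Z) >= stats::qnorm(0.95)) "p<0.1"
         else "n.s."
  marker <- c("p<0.01" = "*", "p<0.05" = "x", "p<0.1" = "+", "n.s." = "-")[[cls]]
  structure(list(S = S, sigma = sigma, Z = Z, p = p,
                 significance_class = cls, marker = marker, n = n,
                 variance = variance),
            class = "trend_test")
}

#' Sen's slope estimator
#'
#' Median of all pairwise slopes `(y_j - y_k)/(t_j - t_k)` for `j > k`,
#' using the explicit odd/even median rule on the sorted slope list. The
#' intercept is the median of `y_i - slope * t_i` (Conover's estimator),
#' and the per-decade rate is ten times the annual slope.
#'
#' @param y Numeric values.
#' @param t Time points (default `seq_along(y)`); need not be consecutive.
#' @return List with `slope` (units/year), `intercept`, `per_decade`,
#'   `n_pairs`.
#' @export
sen_slope <- function(y, t = seq_along(y)) {
  n <- length(y)
  if (n < 2) stop("need at least two values", call. = FALSE)
  if (length(t) != n) stop("`t` must match `y` in length", call. = FALSE)
  ij <- utils::combn(n, 2)
  dt <- t[ij[2, ]] - t[ij[1, ]]
  keep <- dt != 0
  if (!any(keep)) stop("no pair with distinct time points", call. = FALSE)
  slopes <- sort((y[ij[2, ]] - y[ij[1, ]])[keep] / dt[keep])
  N <- length(slopes)
  slope <- if (N %% 2 == 1) {
    slopes[(N + 1) / 2]
  } else {
    (slopes[N / 2] + slopes[N / 2 + 1]) / 2
  }
  list(slope = slope,
       intercept = stats::median(y - slope * t),
       per_decade = 10 * slope,
       n_pairs = N)
}

#' Trend table for many station series
#'
#' Applies the Mann-Kendall test and Sen's slope to every
#' station-by-variable annual series in a tidy table.
#'
#' @param tidy Data.frame with columns `station_id, variable, year, value`.
#' @param variance Variance mode passed to [mk_test()].
#' @param min_n Series shorter than this are skipped (default 4).
#' @return Data.frame with one row per station-variable: `S`, `Z`,
#'   `slope`, `intercept`, `per_decade`, `significance_class`, `marker`,
#'   `n`.
#' @export
trend_table <- function(tidy, variance = "tie_adjusted", min_n = 4) {
  needed <- c("station_id", "variable", "year", "value")
  if (!all(needed %in% names(tidy))) {
    stop("tidy table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(tidy, list(tidy$station_id, tidy$variable), drop = TRUE)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$year), ]
    g <- g[!is.na(g$value), ]
    if (nrow(g) < min_n) return(NULL)
    tt <- mk_test(g$value, variance = variance)
    ss <- sen_slope(g$value, g$year)
    data.frame(station_id = g$station_id[1], variable = g$variable[1],
               n = tt$n, S = tt$S, Z = tt$Z,
               slope = ss$slope, intercept = ss$intercept,
               per_decade = ss$per_decade,
               significance_class = tt$significance_class,
               marker = tt$marker, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
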