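#' Sokolove-Bushell chi-square periodogram
#'
#' For each candidate period P (a whole number of bins, stepped by one bin
#' across the scan range), the series is truncated to an integer number of
#' cycles and folded into p columns. The statistic is
#' \deqn{Q_p = \frac{n^2}{p}\,\frac{\sum_h (\bar x_h - \bar x)^2}
#'                        {\sum_i (x_i - \bar x)^2}}
#' with n the truncated length, p the number of bins per cycle, \eqn{\bar
#' x_h} the column means and \eqn{\bar x} the grand mean of the truncated
#' window. Under the null of no rhythm at P, \eqn{Q_p \sim \chi^2_{p-1}},
#' which gives the per-candidate significance line. The best period is the
#' significant candidate maximizing \eqn{Q_p}; ties are broken toward 24 h.
#'
#' @param series an [activity_series()]; missing bins must not exceed the
#'   missing-data limit and are mean-imputed for folding.
#' @param period_min,period_max scan range, hours (default 20-28, the
#'   conventional rodent free-running range).
#' @param alpha_sig significance level for the chi-square line.
#' @return object of class `"sb_periodogram"`: data frame fields `periods`,
#'   `qp`, `sig_line`, plus `best_period`, `best_qp`, `alpha_sig`, `n`.
#' @references Sokolove PG, Bushell WN (1978) J Theor Biol 72:131-160.
#' @export
sokolove_bushell <- function(series, period_min = 20, period_max = 28,
                             alpha_sig = 0.05) {
  stopifnot(inherits(series, "activity_series"))
  check_missing(series)
  x <- series$counts
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  dt <- series$bin_width / 60
  if (length(x) * dt < 2 * period_max)
    stop("series must cover at least two cycles of period_max", call. = FALSE)
  if (stats::var(x) == 0)
    stop("constant series: periodogram statistic undefined", call. = FALSE)
  p_bins <- seq.int(ceiling(period_min / dt), floor(period_max / dt))
  qp <- vapply(p_bins, function(p) qp_stat(x, p), numeric(1))
  periods <- p_bins * dt
  sig <- stats::qchisq(1 - alpha_sig, df = p_bins - 1)
  ok <- qp > sig
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[order(-qp[cand], abs(periods[cand] - 24))][1]
  } else {
    best <- order(-qp, abs(periods - 24))[1]
    warning("no candidate period reaches significance; reporting the maximum")
  }
  structure(list(periods = periods, qp = qp, sig_line = sig,
                 best_period = periods[best], best_qp = qp[best],
                 alpha_sig = alpha_sig, n = length(x)),
            class = "sb_periodogram")
}

# Qp at a single candidate period of p bins (fold, truncated to whole cycles)
qp_stat <- function(x, p) {
  n <- (length(x) %/% p) * p
  if (n < 2 * p) return(NA_real_)
  xt <- x[seq_len(n)]
  xbar <- mean(xt)
  col_means <- rowMeans(matrix(xt, nrow = p))
  denom <- sum((xt - xbar)^2)
  if (denom == 0) return(NA_real_)
  (n^2 / p) * sum((col_means - xbar)^2) / denom
}

#' @export
print.sb_periodogram <- function(x, ...) {
  cat(sprintf(
    "Sokolove-Bushell periodogram: best period %.4f h (Qp = %.1f, alpha = %g)\n",
    x$best_period, x$best_qp, x$alpha_sig))
  invisible(x)
}

#' Entrained (LD) period via the chi-square periodogram
#'
#' Runs [sokolove_bushell()] on the sub-series of an LD stage with a scan
#' bracketing 24 h. If handed a DD stage the result reflects the
#' free-running period, not the entrained one; segmenting the right stage is
#' the caller's responsibility.
#'
#' @param series an [activity_series()] with a schedule.
#' @param stage stage label to segment (default the whole series).
#' @param period_min,period_max scan range, hours.
#' @param ... passed to [sokolove_bushell()].
#' @return best period in hours.
#' @export
ld_period <- function(series, stage = NULL, period_min = 23, period_max = 25,
                      ...) {
  if (!is.null(stage))
    series <- segment_stage(series, stage)
  sokolove_bushell(series, period_min, period_max, ...)$best_period
}
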