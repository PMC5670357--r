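#' Interdaily stability (IS)
#'
#' Nonparametric index of day-to-day constancy of the activity pattern: the
#' ratio of the variance around the mean cycle profile to the overall
#' variance,
#' \deqn{IS = \frac{n \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
#'                 {p \sum_{i=1}^{n} (x_i - \bar x)^2}}
#' where n is the number of hourly data points (truncated to whole cycles),
#' p the number of points per cycle, \eqn{\bar x_h} the per-hour-of-cycle
#' means and \eqn{\bar x} the grand mean. IS is 1 for a signal that repeats
#' identically every cycle and tends to 0 for white noise. It equals the
#' chi-square periodogram statistic at that period divided by n.
#'
#' The period is rounded to the nearest whole hour to form p (hourly folding
#' requires an integer column count); a message reports the rounding when it
#' is material.
#'
#' @param series an [activity_series()]; rebinned to hourly internally.
#' @param period folding period in hours (default 24; pass the
#'   periodogram's best period for free-running records).
#' @return IS, dimensionless in `[0, 1]` up to numerical tolerance.
#' @references Van Someren EJW et al. (1999) Chronobiol Int 16:505-518.
#' @export
interdaily_stability <- function(series, period = 24) {
  x <- hourly_values(series)
  p <- as.integer(round(period))
  if (abs(period - p) > 1e-9)
    message(sprintf("period %.3f h rounded to %d h for hourly folding",
                    period, p))
  n <- (length(x) %/% p) * p
  if (n < 2 * p) stop("need at least two full cycles", call. = FALSE)
  xt <- x[seq_len(n)]
  xbar <- mean(xt)
  denom <- sum((xt - xbar)^2)
  if (denom == 0) stop("zero overall variance: IS undefined", call. = FALSE)
  hm <- rowMeans(matrix(xt, nrow = p))
  n * sum((hm - xbar)^2) / (p * denom)
}

#' Intradaily variability (IV)
#'
#' Nonparametric index of rhythm fragmentation: the mean square of the
#' first difference between successive hours relative to the overall
#' variance,
#' \deqn{IV = \frac{n \sum_{i=2}^{n} (x_i - x_{i-1})^2}
#'                 {(n-1) \sum_{i=1}^{n} (x_i - \bar x)^2}.}
#' IV approaches 0 for a slowly varying sinusoid, is about 2 for Gaussian
#' white noise, and approaches 4 for a maximally alternating two-level
#' sequence.
#'
#' @inheritParams interdaily_stability
#' @return IV, dimensionless, non-negative.
#' @export
intradaily_variability <- function(series) {
  x <- hourly_values(series)
  n <- length(x)
  if (n < 3) stop("need at least 3 hourly values", call. = FALSE)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) stop("zero overall variance: IV undefined", call. = FALSE)
  n * sum(diff(x)^2) / ((n - 1) * denom)
}

# hourly, NA-checked numeric vector from an activity series
hourly_values <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  if (series$bin_width != 60) series <- rebin(series, 60)
  check_missing(series)
  x <- series$counts
  if (anyNA(x)) x <- x[!is.na(x)] # gaps excluded after the missing-data gate
  x
}

#' Nonparametric circadian rhythm analysis summary
#'
#' Convenience wrapper computing IS at a stated period (typically the
#' periodogram's best period) together with IV on the same hourly series.
#'
#' @inheritParams interdaily_stability
#' @return list with `IS`, `IV`, `period_used` (rounded hours), `n`.
#' @export
npcra <- function(series, period = 24) {
  list(IS = interdaily_stability(series, period),
       IV = intradaily_variability(series),
       period_used = as.integer(round(period)),
       n = length(hourly_values(series)))
}
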