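#' Continuous wavelet spectrum of an activity series
#'
#' Morlet continuous wavelet transform over a geometric scale grid mapped to
#' periods, following the standard normalization and cone-of-influence
#' conventions for geophysical-style spectral analysis of discrete series.
#' The series is demeaned and zero-padded to the next power of two; the
#' transform is evaluated in the Fourier domain. The Morlet center frequency
#' `omega0 = 6` makes the scale-to-period factor approximately 1.033.
#'
#' @param series an [activity_series()].
#' @param period_range scanned period range in hours (default 16-32,
#'   bracketing the circadian band).
#' @param dj scale-grid resolution in octaves (default 1/64).
#' @param omega0 Morlet nondimensional center frequency.
#' @return object of class `"cwt_spectrum"`: `times` (hours), `periods`
#'   (hours, geometric grid), `power` (period x time matrix), `coi`
#'   (maximum trustworthy period per time), `ar1` (estimated lag-1
#'   autocorrelation), `variance` (series variance), `dt` (hours).
#' @references Torrence C, Compo GP (1998) Bull Am Meteorol Soc 79:61-78.
#' @export
cwt_spectrum <- function(series, period_range = c(16, 32), dj = 1 / 64,
                         omega0 = 6) {
  stopifnot(inherits(series, "activity_series"))
  check_missing(series)
  x <- series$counts
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  dt <- series$bin_width / 60
  n <- length(x)
  if (n * dt < 3 * max(period_range))
    stop("series must cover at least three cycles of the longest scanned period",
         call. = FALSE)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s_min <- period_range[1] / fourier_factor
  s_max <- period_range[2] / fourier_factor
  n_scales <- floor(log2(s_max / s_min) / dj) + 1L
  scales <- s_min * 2^((seq_len(n_scales) - 1) * dj)
  periods <- scales * fourier_factor

  ar1 <- ar1_coef(x)
  variance <- stats::var(x)
  x0 <- x - mean(x)
  n_pad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x0, rep(0, n_pad - n)))
  k <- seq_len(n_pad) - 1
  omega <- ifelse(k <= n_pad / 2, 2 * pi * k / (n_pad * dt),
                  -2 * pi * (n_pad - k) / (n_pad * dt))
  power <- matrix(0, nrow = n_scales, ncol = n,
                  dimnames = list(NULL, NULL))
  for (j in seq_len(n_scales)) {
    psi_hat <- pi^(-1 / 4) * sqrt(2 * pi * scales[j] / dt) *
      exp(-((scales[j] * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / n_pad
    power[j, ] <- Mod(w[seq_len(n)])^2
  }
  t_hours <- (seq_len(n) - 1) * dt
  coi <- fourier_factor * sqrt(2) * pmin(t_hours, (n - 1) * dt - t_hours)
  structure(list(times = t_hours, periods = periods, power = power,
                 coi = coi, ar1 = ar1, variance = variance, dt = dt,
                 omega0 = omega0),
            class = "cwt_spectrum")
}

# lag-1 autocorrelation of the analyzed series (AR(1) background estimate)
ar1_coef <- function(x) {
  r <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  max(min(r, 0.99), 0)
}

#' Pointwise significance mask for a wavelet spectrum
#'
#' Cells are significant where power exceeds the chi-square (2 df)
#' threshold against a red-noise background: an AR(1) process with the
#' lag-1 coefficient estimated from the analyzed series, whose theoretical
#' spectrum is evaluated at each scale's equivalent Fourier frequency.
#' Cells outside the cone of influence are never significant.
#'
#' @param spectrum a [cwt_spectrum()].
#' @param level significance level (default 0.05).
#' @return logical matrix (period x time), `TRUE` where significant.
#' @export
significance_mask <- function(spectrum, level = 0.05) {
  stopifnot(inherits(spectrum, "cwt_spectrum"))
  rho <- spectrum$ar1
  freq <- spectrum$dt / spectrum$periods # nondimensional frequency
  bg <- (1 - rho^2) / (1 + rho^2 - 2 * rho * cos(2 * pi * freq))
  thresh <- spectrum$variance * bg * stats::qchisq(1 - level, df = 2) / 2
  mask <- sweep(spectrum$power, 1, thresh, ">")
  inside <- outer(spectrum$periods, spectrum$coi, "<=")
  mask & inside
}

#' Instantaneous-period track from a wavelet spectrum
#'
#' For every time step, the period of maximum significance: the cell with
#' the largest wavelet power among cells that are significant and inside
#' the cone of influence. Times with no significant cell are flagged
#' invalid.
#'
#' @param spectrum a [cwt_spectrum()].
#' @param level significance level for the mask.
#' @return object of class `"period_track"`: `times`, `period` (NA where
#'   invalid), `valid`, and `period_step` (mean period-grid spacing, used as
#'   the default histogram resolution downstream).
#' @export
instant_period <- function(spectrum, level = 0.05) {
  mask <- significance_mask(spectrum, level)
  score <- spectrum$power
  score[!mask] <- -Inf
  idx <- apply(score, 2, which.max)
  valid <- apply(mask, 2, any)
  period <- ifelse(valid, spectrum$periods[idx], NA_real_)
  structure(list(times = spectrum$times, period = period, valid = valid,
                 period_step = mean(diff(spectrum$periods))),
            class = "period_track")
}

#' Shannon entropy of a discrete distribution
#'
#' \eqn{SE = -\sum_i p_i \ln p_i} over bins with non-zero probability, in
#' nats; 0 for a point mass, `ln m` for a uniform law over m bins.
#'
#' @param probabilities non-negative, summing to 1 (tolerance 1e-9).
#' @return entropy in nats.
#' @export
shannon_entropy <- function(probabilities) {
  if (any(probabilities < 0))
    stop("negative probability", call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must sum to 1", call. = FALSE)
  p <- probabilities[probabilities > 0]
  -sum(p * log(p))
}

#' Period-variability index V
#'
#' Quantifies the spread of the instantaneous-period distribution through
#' the Shannon entropy of its histogram: \eqn{V = 1 - SE / \ln N} with N
#' the number of valid observations. V is 1 when every observation falls in
#' a single histogram bin (a single stable period) and 0 when each of the N
#' observations occupies its own bin (maximal period spread).
#'
#' @param track a `period_track` from [instant_period()], or a plain numeric
#'   vector of instantaneous periods (hours).
#' @param bin_width histogram bin width in hours; defaults to twice the
#'   period-grid resolution of the wavelet scale grid when a track is
#'   given.
#' @return list of class `"variability_result"`: `V`, `SE` (nats), `N`,
#'   `breaks`, `probabilities`.
#' @export
variability_index <- function(track, bin_width = NULL) {
  if (inherits(track, "period_track")) {
    periods <- track$period[track$valid]
    if (is.null(bin_width)) bin_width <- 2 * track$period_step
  } else {
    periods <- as.numeric(track)
    periods <- periods[!is.na(periods)]
    if (is.null(bin_width))
      stop("bin_width is required for a plain period vector", call. = FALSE)
  }
  N <- length(periods)
  if (N < 2) stop("need at least 2 valid periods", call. = FALSE)
  lo <- floor(min(periods) / bin_width) * bin_width
  breaks <- seq(lo, max(periods) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(periods, breaks), length(breaks))
  prob <- counts / N
  se <- shannon_entropy(prob)
  v <- min(max(1 - se / log(N), 0), 1)
  structure(list(V = v, SE = se, N = N, breaks = breaks,
                 probabilities = prob),
            class = "variability_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("Period variability: V = %.3f (SE = %.3f nats, N = %d)\n",
              x$V, x$SE, x$N))
  invisible(x)
}
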