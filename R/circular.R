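#' Rayleigh test of phase concentration
#'
#' Tests whether a sample of circular phases is concentrated around a mean
#' direction. The mean resultant length is \eqn{r = |\sum_k e^{i\theta_k}|/n};
#' the p value uses the standard approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))} with
#' \eqn{R = nr}, accurate even at small n.
#'
#' @param phases angles in radians (any real values; reduced mod 2pi), or
#'   pass `hours` with a `period` instead.
#' @param hours phases expressed in hours on a cycle of length `period`.
#' @param period cycle length in hours used to map `hours` to angles.
#' @return list of class `"rayleigh_test"`: `r`, `mean_angle` (radians in
#'   `[0, 2pi)`), `mean_hours` (on the given period, if supplied), `n`,
#'   `p`.
#' @export
rayleigh_test <- function(phases = NULL, hours = NULL, period = 24) {
  if (is.null(phases)) {
    if (is.null(hours)) stop("supply phases or hours", call. = FALSE)
    phases <- 2 * pi * (hours %% period) / period
  }
  phases <- phases[!is.na(phases)]
  n <- length(phases)
  if (n < 2) stop("need at least 2 phases", call. = FALSE)
  z <- sum(exp(1i * phases))
  r <- Mod(z) / n
  mu <- Arg(z) %% (2 * pi)
  rr <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rr^2)) - (1 + 2 * n))
  p <- min(p, 1)
  structure(list(r = r, mean_angle = mu,
                 mean_hours = mu * period / (2 * pi), n = n, p = p),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: r = %.3f, mean = %.2f h, n = %d, p = %.4g\n",
              x$r, x$mean_hours, x$n, x$p))
  invisible(x)
}

# circular mean of hour values on a cycle of `period` hours, as a fraction
# of the cycle in [0, 1)
circ_mean_frac <- function(hours, period) {
  th <- 2 * pi * (hours %% period) / period
  (Arg(sum(exp(1i * th))) / (2 * pi)) %% 1
}

#' LD-to-DD phase difference of activity onset
#'
#' Compares the expressed phase under entrainment with the phase the clock
#' reveals once released into constant darkness: the circular mean onset
#' over the last LD days (folded at 24 h) minus the circular mean onset
#' over the first DD days (folded at the animal's own free-running period
#' `tau`), expressed in hours on the 24-h cycle and wrapped to `(-12, 12]`.
#' A purely clock-driven LD onset gives a small difference; masking of the
#' expressed LD onset inflates it.
#'
#' @param ld_onsets onset times over the last LD days (typically 10), in
#'   absolute hours since the record origin (`day * 24 + clock_hour`); the
#'   day term matters because folding at a non-24-h period must see real
#'   elapsed time.
#' @param dd_onsets onset times over the first DD days, absolute hours.
#' @param tau free-running period used to fold the DD onsets, hours.
#' @param min_onsets minimum valid onsets required per window.
#' @return phase difference in hours, `(-12, 12]`.
#' @export
delta_psi <- function(ld_onsets, dd_onsets, tau, min_onsets = 5) {
  ld_onsets <- ld_onsets[!is.na(ld_onsets)]
  dd_onsets <- dd_onsets[!is.na(dd_onsets)]
  if (length(ld_onsets) < min_onsets || length(dd_onsets) < min_onsets)
    stop("insufficient onsets in the LD or DD window", call. = FALSE)
  f_ld <- circ_mean_frac(ld_onsets, 24)
  f_dd <- circ_mean_frac(dd_onsets, tau)
  d <- (f_ld - f_dd) * 24
  dd <- ((d + 12) %% 24) - 12
  if (dd == -12) dd <- 12
  dd
}

#' Group-level Rayleigh analysis of per-animal phase differences
#'
#' Maps each animal's LD-to-DD phase difference onto the 24-h circle and
#' applies the Rayleigh test, asking whether the cohort's differences
#' cluster around a common direction.
#'
#' @param deltas per-animal phase differences in hours (from
#'   [delta_psi()]).
#' @return a [rayleigh_test()] result.
#' @export
group_delta_psi <- function(deltas) {
  rayleigh_test(hours = deltas, period = 24)
}
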