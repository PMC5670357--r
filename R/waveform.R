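#' Mean activity waveform
#'
#' Folds the series at `period_base` (24 h for entrained records, the
#' animal's own free-running period for DD records) and averages activity in
#' each phase bin over the window, giving the mean daily profile from which
#' onset, alpha/rho and phase-angle metrics are read. Missing bins are
#' excluded from their phase-bin mean.
#'
#' @param series an [activity_series()].
#' @param period_base folding period, hours.
#' @param window_days number of days averaged (default: all).
#' @return object of class `"waveform"`: `phase` (bin start, hours in
#'   `[0, period_base)`), `activity` (mean per phase bin), `baseline`
#'   (mean of the profile), `period_base`, `bin_hours`, `n_days`.
#' @export
mean_waveform <- function(series, period_base = 24, window_days = NULL) {
  stopifnot(inherits(series, "activity_series"))
  check_missing(series)
  dt <- series$bin_width / 60
  if (!is.null(window_days)) {
    n_keep <- min(length(series$counts), round(window_days * 24 / dt))
    series <- activity_series(series$counts[seq_len(n_keep)],
                              bin_width = series$bin_width,
                              start_day = series$start_day,
                              start_hour = series$start_hour,
                              schedule = series$schedule,
                              allow_negative = TRUE)
  }
  x <- series$counts
  if (length(x) * dt < 2 * period_base)
    stop("window must cover at least two full periods", call. = FALSE)
  phase <- (bin_times(series) - series$start_day * 24) %% period_base
  bin_idx <- floor(phase / dt + 1e-9)
  n_bins <- ceiling(period_base / dt - 1e-9)
  bin_idx[bin_idx >= n_bins] <- n_bins - 1
  means <- tapply(x, factor(bin_idx, levels = 0:(n_bins - 1)),
                  mean, na.rm = TRUE)
  act <- as.numeric(means)
  structure(list(phase = (0:(n_bins - 1)) * dt, activity = act,
                 baseline = mean(act, na.rm = TRUE),
                 period_base = period_base, bin_hours = dt,
                 n_days = length(x) * dt / period_base),
            class = "waveform")
}

#' Detect activity onset on a mean waveform
#'
#' The onset is the phase at which the activity curve rises above the mean
#' baseline and stays above it for at least `min_run` hours. The search is
#' circular; an isolated supra-baseline blip shorter than `min_run` is
#' rejected. When several runs qualify (fragmented profiles), the longest
#' is taken, which makes the rule equivariant under circular rotation of
#' the waveform.
#'
#' @param waveform a [mean_waveform()].
#' @param min_run minimum supra-baseline run, hours (default 2).
#' @return onset phase in hours (start of the qualifying run).
#' @export
detect_onset <- function(waveform, min_run = 2) {
  stopifnot(inherits(waveform, "waveform"))
  above <- waveform$activity > waveform$baseline
  above[is.na(above)] <- FALSE # missing phase bins cannot carry an onset
  if (all(above) || !any(above))
    stop("no onset: waveform does not cross its baseline", call. = FALSE)
  n <- length(above)
  starts <- which(above & !above[c(n, seq_len(n - 1))])
  run_len <- vapply(starts, function(s) {
    len <- 0L
    while (above[(s - 1 + len) %% n + 1] && len < n) len <- len + 1L
    len
  }, integer(1))
  ok <- run_len * waveform$bin_hours >= min_run
  if (!any(ok))
    stop(sprintf("no supra-baseline run of at least %g h", min_run),
         call. = FALSE)
  best <- starts[ok][which.max(run_len[ok])]
  waveform$phase[best]
}

#' Active-phase / rest-phase partition of a waveform
#'
#' Alpha (subjective night) is the total time the mean activity curve spends
#' above its baseline, rho (subjective day) the remainder of the cycle;
#' together they tile the period. `activity_in_alpha` is the share of total
#' activity falling in the supra-baseline bins.
#'
#' @param waveform a [mean_waveform()].
#' @return list with `alpha` (hours), `rho` (hours), `activity_in_alpha`
#'   (fraction).
#' @export
alpha_rho <- function(waveform) {
  stopifnot(inherits(waveform, "waveform"))
  above <- waveform$activity > waveform$baseline
  if (all(above) || !any(above))
    stop("constant-like waveform: alpha/rho undefined", call. = FALSE)
  alpha <- sum(above) * waveform$bin_hours
  total <- sum(waveform$activity)
  list(alpha = alpha, rho = waveform$period_base - alpha,
       activity_in_alpha = sum(waveform$activity[above]) / total)
}

#' Phase angle of entrainment
#'
#' Signed difference, in minutes, between lights-off (ZT 12) and the
#' activity onset: positive when the onset precedes lights-off (a phase
#' advance of activity relative to the dark phase), negative when activity
#' starts after dark. Wrapped to `(-720, 720]`.
#'
#' @param onset activity onset in ZT hours, `[0, 24)`.
#' @return phase angle psi in minutes.
#' @export
phase_angle <- function(onset) {
  psi <- (12 - onset) * 60
  ((psi + 720) %% 1440) - 720 + ifelse((psi + 720) %% 1440 == 0, 1440, 0)
}

#' Diurnal activity fraction of a waveform
#'
#' The share of total activity contributed by phase bins whose mean
#' activity lies below the waveform baseline (the rest-phase area),
#' reported as a percentage. An alternative reading — the share of activity
#' during the lights-on span — is available via `rule = "lights_on"` and a
#' schedule.
#'
#' @param waveform a [mean_waveform()] of an LD stage (phase axis = ZT).
#' @param rule `"below_baseline"` (default) or `"lights_on"`.
#' @param schedule [light_schedule()], required for `rule = "lights_on"`.
#' @param day day index used to resolve the lit span (default 0).
#' @return percentage in `[0, 100]`.
#' @export
diurnal_activity <- function(waveform, rule = c("below_baseline", "lights_on"),
                             schedule = NULL, day = 0) {
  stopifnot(inherits(waveform, "waveform"))
  rule <- match.arg(rule)
  total <- sum(waveform$activity)
  if (total == 0 || all(waveform$activity == waveform$activity[1]))
    stop("constant waveform: diurnal activity undefined", call. = FALSE)
  if (rule == "below_baseline") {
    sel <- waveform$activity < waveform$baseline
  } else {
    if (is.null(schedule)) stop("schedule required", call. = FALSE)
    s <- schedule_on_day(schedule, day)
    span <- (s$lights_off - s$lights_on) %% 24
    sel <- waveform$phase < span # phase axis assumed ZT (0 = lights-on)
  }
  100 * sum(waveform$activity[sel]) / total
}
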