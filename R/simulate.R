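#' Parameters for synthetic actogram generation
#'
#' Collects the ground-truth parameters of the generator: a nocturnal animal
#' whose activity is an inhomogeneous Poisson process, high-rate inside the
#' active phase (duration `alpha_hours` of each circadian cycle of period
#' `tau`) and low-rate outside. Instability enters through `drift_sd` (a
#' per-cycle Gaussian random walk on the instantaneous period) and
#' `fragmentation` (per-bin probability that an active bin transiently drops
#' to the rest rate). Under LD, `masking_gain` multiplicatively attenuates
#' activity while lights are on (1 = no masking). After a schedule shift, the
#' true onset phase relaxes to the new cycle along a variable-slope sigmoid
#' with midpoint `resync_ps50` days and slope `resync_slope`.
#'
#' @param n_days days to simulate.
#' @param bin_width bin width, minutes.
#' @param tau free-running period, hours.
#' @param alpha_hours active-phase (subjective night) duration, hours;
#'   must be `< tau`.
#' @param rate_active,rate_rest expected counts per bin inside / outside the
#'   active phase (Poisson intensities).
#' @param drift_sd per-cycle SD of the random walk on instantaneous period,
#'   hours.
#' @param fragmentation probability in `[0, 1]` that any given hour-scale
#'   bout of the active phase is replaced by a rest bout.
#' @param masking_gain multiplicative attenuation of activity during
#'   lights-on, in `[0, 1]`.
#' @param psi_min stable phase angle of activity onset, minutes before
#'   lights-off (LD simulations).
#' @param resync_ps50 days to half-resynchronization after a shift.
#' @param resync_slope Hill slope of the resynchronization sigmoid.
#' @param seed integer seed; all randomness in a simulation flows from it.
#' @return a list of class `"sim_params"`.
#' @export
sim_params <- function(n_days = 15, bin_width = 5, tau = 23.7,
                       alpha_hours = 13, rate_active = 10, rate_rest = 0.5,
                       drift_sd = 0, fragmentation = 0, masking_gain = 1,
                       psi_min = 0, resync_ps50 = 3, resync_slope = 3,
                       seed = 1L) {
  p <- list(n_days = n_days, bin_width = bin_width, tau = tau,
            alpha_hours = alpha_hours, rate_active = rate_active,
            rate_rest = rate_rest, drift_sd = drift_sd,
            fragmentation = fragmentation, masking_gain = masking_gain,
            psi_min = psi_min, resync_ps50 = resync_ps50,
            resync_slope = resync_slope, seed = as.integer(seed))
  if (p$alpha_hours <= 0 || p$alpha_hours >= p$tau)
    stop("need 0 < alpha_hours < tau", call. = FALSE)
  if (p$rate_rest < 0 || p$rate_active < p$rate_rest)
    stop("need rate_active >= rate_rest >= 0", call. = FALSE)
  if (p$masking_gain < 0 || p$masking_gain > 1)
    stop("masking_gain must lie in [0, 1]", call. = FALSE)
  if (p$fragmentation < 0 || p$fragmentation > 1)
    stop("fragmentation must lie in [0, 1]", call. = FALSE)
  if (p$drift_sd < 0 || p$n_days < 1 || p$resync_ps50 <= 0)
    stop("invalid simulation parameters", call. = FALSE)
  class(p) <- "sim_params"
  p
}

# fraction of each bin [t, t+dt) covered by the union of active windows
# windows: matrix with columns start, end (absolute hours), non-overlapping
active_fraction <- function(t0, dt, n_bins, windows) {
  frac <- numeric(n_bins)
  for (k in seq_len(nrow(windows))) {
    a <- windows[k, 1]; b <- windows[k, 2]
    i0 <- max(1L, floor((a - t0) / dt) + 1L)
    i1 <- min(n_bins, ceiling((b - t0) / dt))
    if (i1 < i0) next
    i <- i0:i1
    lo <- t0 + (i - 1) * dt
    frac[i] <- frac[i] + pmin(b, lo + dt) - pmax(a, lo)
  }
  pmin(frac / dt, 1)
}

# split active windows into ~1 h bouts and drop each with the given
# probability: fragmentation acts at the bout scale a rest intrusion has in
# rodent records, not per sensor bin
fragment_windows <- function(windows, fragmentation, bout_h = 1) {
  if (fragmentation <= 0) return(windows)
  pieces <- list()
  for (k in seq_len(nrow(windows))) {
    cuts <- seq(windows[k, 1], windows[k, 2], by = bout_h)
    if (cuts[length(cuts)] < windows[k, 2])
      cuts <- c(cuts, windows[k, 2])
    keep <- stats::runif(length(cuts) - 1) >= fragmentation
    if (any(keep))
      pieces[[length(pieces) + 1]] <-
        cbind(cuts[-length(cuts)][keep], cuts[-1][keep])
  }
  if (length(pieces) == 0) return(windows[0, , drop = FALSE])
  do.call(rbind, pieces)
}

# draw Poisson counts from per-bin active fractions
draw_counts <- function(frac, params) {
  lambda <- params$rate_active * frac + params$rate_rest * (1 - frac)
  stats::rpois(length(lambda), lambda)
}

#' Simulate a free-running (DD) actogram
#'
#' Activity cycles at the free-running period `tau`: the k-th active window
#' starts at the k-th true onset and lasts `alpha_hours`. With `drift_sd > 0`
#' the cycle-to-cycle period follows a Gaussian random walk, eroding period
#' stability; `fragmentation` punches transient rest bouts into the active
#' phase. Identical seeds give identical output.
#'
#' @param params a [sim_params()].
#' @param onset0 absolute hour of the first activity onset (default 12).
#' @return list with `series` (the [activity_series()], DD schedule attached)
#'   and `truth` (data frame: cycle index, true onset in absolute hours, true
#'   instantaneous period in hours).
#' @export
simulate_dd <- function(params, onset0 = 12) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  total_h <- params$n_days * 24
  n_cycles <- ceiling(total_h / params$tau) + 1L
  period <- params$tau + cumsum(c(0, stats::rnorm(n_cycles - 1, 0,
                                                  params$drift_sd)))
  period <- pmax(period, 16) # keep the walk physiological
  onsets <- onset0 + c(0, cumsum(period[-n_cycles]))
  windows <- cbind(onsets, onsets + params$alpha_hours)
  windows <- fragment_windows(windows, params$fragmentation)
  dt <- params$bin_width / 60
  n_bins <- as.integer(round(total_h / dt))
  frac <- active_fraction(0, dt, n_bins, windows)
  counts <- draw_counts(frac, params)
  sched <- light_schedule(
    data.frame(start_day = 0, regime = "DD", lights_on = NA, lights_off = NA),
    stage_bounds = list(DD = c(0, params$n_days - 1)))
  list(
    series = activity_series(counts, bin_width = params$bin_width,
                             schedule = sched),
    truth = data.frame(cycle = seq_len(n_cycles), onset = onsets,
                       period = period)
  )
}

# resynchronization sigmoid: onset phase (minutes before lights-off) on day
# x >= 1 after a shift of `shift_h` hours, relaxing from psi - 60*shift_h to
# psi along the variable-slope curve in log10(days): the half-point falls
# exactly at x = ps50 days
resync_curve <- function(x, psi_min, shift_h, ps50, slope) {
  bottom <- psi_min - 60 * shift_h
  bottom + (psi_min - bottom) /
    (1 + 10^((log10(ps50) - log10(x)) * slope))
}

#' Simulate an entrained actogram with a jet-lag shift
#'
#' Before any shift the true activity onset holds a fixed phase angle
#' `psi_min` minutes before lights-off. After each shift event the onset
#' phase, expressed relative to the post-shift lights-off, relaxes from its
#' displaced value back to `psi_min` along the variable-slope sigmoid with
#' midpoint `resync_ps50` days, so the generator's PS50 ground truth is
#' exact by construction. Activity during lights-on is multiplied by
#' `masking_gain`.
#'
#' @param params a [sim_params()].
#' @param schedule a [light_schedule()] containing at least one shift event
#'   inside the simulated range.
#' @return list with `series` and `truth` (data frame: day, true onset clock
#'   hour, onset phase in minutes before the current lights-off).
#' @export
simulate_jetlag <- function(params, schedule) {
  stopifnot(inherits(params, "sim_params"),
            inherits(schedule, "light_schedule"))
  if (is.null(schedule$shifts) || nrow(schedule$shifts) == 0)
    stop("schedule has no shift event", call. = FALSE)
  if (min(schedule$shifts$day) >= params$n_days)
    stop("shift event outside the simulated range", call. = FALSE)
  sim_entrained(params, schedule)
}

#' Simulate a stably entrained (LD) actogram
#'
#' As [simulate_jetlag()] but under an unshifted 12:12 cycle: the true
#' onset holds the phase angle `psi_min` before lights-off on every day.
#'
#' @inheritParams simulate_jetlag
#' @param lights_on lights-on clock hour.
#' @return list with `series` and `truth` as in [simulate_jetlag()].
#' @export
simulate_ld <- function(params, lights_on = 8) {
  sched <- light_schedule(
    data.frame(start_day = 0, regime = "LD", lights_on = lights_on,
               lights_off = (lights_on + 12) %% 24),
    stage_bounds = list(LD = c(0, params$n_days - 1)))
  sim_entrained(params, sched)
}

sim_entrained <- function(params, schedule) {
  set.seed(params$seed)
  days <- 0:(params$n_days - 1)
  phase <- numeric(length(days))   # minutes before current lights-off
  onset_clock <- numeric(length(days))
  for (d in days) {
    s <- schedule_on_day(schedule, d)
    past <- if (is.null(schedule$shifts)) data.frame(day = numeric(0)) else
      schedule$shifts[schedule$shifts$day <= d, , drop = FALSE]
    if (nrow(past) == 0) {
      ph <- params$psi_min
    } else {
      last <- past[which.max(past$day), ]
      ph <- resync_curve(d - last$day + 1, params$psi_min, last$hours,
                         params$resync_ps50, params$resync_slope)
    }
    phase[d + 1] <- ph
    onset_clock[d + 1] <- (s$lights_off - ph / 60) %% 24
  }
  windows <- cbind(days * 24 + onset_clock,
                   days * 24 + onset_clock + params$alpha_hours)
  windows <- fragment_windows(windows, params$fragmentation)
  dt <- params$bin_width / 60
  n_bins <- as.integer(round(params$n_days * 24 / dt))
  frac <- active_fraction(0, dt, n_bins, windows)
  counts <- draw_counts(frac, params)
  # masking: attenuate counts that fall in the lights-on interval of their day
  if (params$masking_gain < 1) {
    t <- (seq_len(n_bins) - 1) * dt
    lit <- vapply(t, function(ti) {
      s <- schedule_on_day(schedule, floor(ti / 24))
      if (s$regime != "LD") return(FALSE)
      zt <- (ti %% 24 - s$lights_on) %% 24
      span <- (s$lights_off - s$lights_on) %% 24
      zt < span
    }, logical(1))
    counts[lit] <- stats::rbinom(sum(lit), counts[lit], params$masking_gain)
  }
  list(
    series = activity_series(counts, bin_width = params$bin_width,
                             schedule = schedule),
    truth = data.frame(day = days, onset_clock = onset_clock,
                       phase_min = phase)
  )
}

#' Simulate a Gaussian white-noise series
#'
#' Arrhythmic reference input for the stability indices: interdaily
#' stability tends to zero and intradaily variability to about 2 on such
#' series. Values are real (negatives permitted internally).
#'
#' @param n number of bins (> 1).
#' @param sd standard deviation of the noise.
#' @param seed integer seed.
#' @param bin_width bin width in minutes (default hourly).
#' @param mean mean level.
#' @return an [activity_series()] with real-valued entries.
#' @export
simulate_noise <- function(n, sd = 1, seed = 1L, bin_width = 60, mean = 0) {
  if (n <= 1) stop("need n > 1", call. = FALSE)
  set.seed(as.integer(seed))
  activity_series(stats::rnorm(n, mean, sd), bin_width = bin_width,
                  allow_negative = TRUE)
}

#' Standard jet-lag light schedule
#'
#' Convenience constructor for a 12:12 LD protocol with a single advance:
#' lights on at `lights_on` for `shift_day` days, then a `shift_h`-hour
#' advance of the light phase (dark phase shortened once).
#'
#' @param n_days protocol length in days.
#' @param shift_day 0-based day on which the shifted cycle begins.
#' @param shift_h advance in hours (positive; default 6).
#' @param lights_on baseline lights-on clock hour.
#' @param resync_days days allowed for resynchronization before the
#'   post-jet-lag stage (`pjl`) begins; phase metrics for that stage are
#'   meaningful only after full resynchronization.
#' @return a [light_schedule()] with stages `pre` (before the shift),
#'   `post` (everything from the shift on) and `pjl` (after
#'   resynchronization).
#' @export
jetlag_schedule <- function(n_days = 32, shift_day = 10, shift_h = 6,
                            lights_on = 8, resync_days = 8) {
  light_schedule(
    data.frame(start_day = 0, regime = "LD", lights_on = lights_on,
               lights_off = (lights_on + 12) %% 24),
    shifts = data.frame(day = shift_day, hours = shift_h),
    stage_bounds = list(pre = c(0, shift_day - 1),
                        post = c(shift_day, n_days - 1),
                        pjl = c(min(shift_day + resync_days, n_days - 2),
                                n_days - 1)))
}
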