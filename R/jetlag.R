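#' Daily activity onsets around a schedule shift
#'
#' Applies the supra-baseline onset rule day by day: each day's activity
#' profile (at `profile_width`-minute resolution, hourly by default) is
#' compared against that day's own mean, and the onset is the start of the
#' first run staying above the mean for at least `min_run` hours. Onsets
#' are expressed in minutes before the post-shift lights-off — the axis on
#' which resynchronization is fitted — and days with no qualifying run are
#' flagged missing rather than imputed.
#'
#' @param series an [activity_series()] under the shifting schedule.
#' @param schedule a [light_schedule()] with at least one shift event.
#' @param window integer day range `c(first, last)` (0-based, inclusive)
#'   straddling the shift; default: the whole series.
#' @param min_run minimum supra-baseline run, hours.
#' @param profile_width bin width of the daily profile, minutes.
#' @return data frame of class `"onset_series"`: `day` (0-based calendar
#'   day), `day_post` (1-based day since the shifted cycle began; <= 0
#'   before), `onset_clock` (clock hours, NA if undetected), `phase_min`
#'   (minutes before post-shift lights-off).
#' @export
daily_onsets <- function(series, schedule = series$schedule, window = NULL,
                         min_run = 2, profile_width = 60) {
  stopifnot(inherits(series, "activity_series"))
  if (is.null(schedule$shifts) || nrow(schedule$shifts) == 0)
    stop("window does not straddle a shift event", call. = FALSE)
  shift_day <- schedule$shifts$day[1]
  days <- if (is.null(window)) NULL else seq.int(window[1], window[2])
  if (!is.null(window) && (window[1] >= shift_day || window[2] < shift_day))
    stop("window does not straddle a shift event", call. = FALSE)
  ob <- onsets_by_day(series, days = days, min_run = min_run,
                      profile_width = profile_width)
  post <- schedule_on_day(schedule, shift_day) # shifted lights times
  ph <- (post$lights_off - ob$onset_clock) * 60
  out <- data.frame(day = ob$day, day_post = ob$day - shift_day + 1L,
                    onset_clock = ob$onset_clock,
                    phase_min = ((ph + 720) %% 1440) - 720)
  class(out) <- c("onset_series", "data.frame")
  out
}

#' Per-day activity onsets
#'
#' Applies the supra-baseline onset rule to each calendar day's own profile
#' (baseline = that day's mean). Days without a qualifying run, or with
#' less than 20 h of data, get `NA`.
#'
#' A single day's profile is far noisier than a multi-day mean waveform, so
#' it is smoothed with a short circular moving average (`smooth_bins` wide)
#' before thresholding; this stabilizes the detected onset against transient
#' rest bouts splitting the active phase.
#'
#' @inheritParams daily_onsets
#' @param days 0-based day indices to analyze (default: every complete day
#'   in the series).
#' @param smooth_bins width (bins) of the circular moving average applied
#'   to the daily profile; 1 disables smoothing.
#' @return data frame: `day`, `onset_clock` (clock hours or NA).
#' @export
onsets_by_day <- function(series, days = NULL, min_run = 2,
                          profile_width = 60, smooth_bins = 3) {
  stopifnot(inherits(series, "activity_series"))
  t <- bin_times(series)
  if (is.null(days))
    days <- seq.int(floor(min(t) / 24), floor(max(t) / 24))
  onset_clock <- rep(NA_real_, length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    sel <- t >= d * 24 & t < (d + 1) * 24
    if (sum(sel) * series$bin_width < 20 * 60) next # incomplete day
    day_series <- activity_series(series$counts[sel],
                                  bin_width = series$bin_width,
                                  start_day = d, start_hour = t[sel][1] %% 24,
                                  allow_negative = TRUE)
    if (profile_width > series$bin_width)
      day_series <- rebin(day_series, profile_width)
    act <- day_series$counts
    if (smooth_bins > 1) {
      k <- rep(1 / smooth_bins, smooth_bins)
      n <- length(act)
      pad <- c(act[(n - smooth_bins + 1):n], act, act[1:smooth_bins])
      act <- stats::filter(pad, k, circular = FALSE)[
        smooth_bins + seq_len(n)]
    }
    wf <- structure(list(phase = (bin_times(day_series) - d * 24) %% 24,
                         activity = act,
                         baseline = mean(act, na.rm = TRUE),
                         period_base = 24,
                         bin_hours = day_series$bin_width / 60),
                    class = "waveform")
    onset <- tryCatch(detect_onset(wf, min_run),
                      error = function(e) NA_real_)
    if (!is.na(onset) && smooth_bins > 1) {
      ## the moving average leaks activity into the bins just before the
      ## true rise; advance to the first bin that is supra-baseline in the
      ## raw profile as well
      raw <- day_series$counts
      raw_base <- mean(raw, na.rm = TRUE)
      j <- which(abs(wf$phase - onset) < 1e-9)
      nb <- length(raw)
      for (step in 0:(smooth_bins - 1)) {
        jj <- (j - 1 + step) %% nb + 1
        if (!is.na(raw[jj]) && raw[jj] > raw_base) {
          onset <- wf$phase[jj]
          break
        }
      }
    }
    onset_clock[i] <- onset
  }
  data.frame(day = days, onset_clock = onset_clock)
}

#' Fit the resynchronization sigmoid
#'
#' Least-squares fit of the variable-slope sigmoid
#' \deqn{y = Bottom + \frac{Top - Bottom}{1 + 10^{(\log PS_{50} - x)\,HillSlope}}}
#' with x on the log10 axis of days after the schedule shift (the standard
#' variable-slope dose-response parameterization), applied to onset phases
#' y (minutes). PS50 = 10^logPS50 is the number of days needed to reach
#' half of the phase resynchronization; the fitted curve passes through
#' (PS50, (Top+Bottom)/2) by construction.
#'
#' @param x days post-shift (1-based), or an `onset_series` from
#'   [daily_onsets()] (post-shift rows with detected onsets are used).
#' @param y onset phases in minutes (ignored when `x` is an
#'   `onset_series`).
#' @return object of class `"resync_fit"`: `bottom`, `top`, `log_ps50`,
#'   `hill_slope`, `ps50` (days), `rss`, `df` (n - 4), `n`, `fitted`
#'   function.
#' @export
fit_resync <- function(x, y = NULL) {
  if (inherits(x, "onset_series")) {
    keep <- x$day_post >= 1 & !is.na(x$phase_min)
    y <- x$phase_min[keep]
    x <- x$day_post[keep]
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 5)
    stop("need onsets on at least 5 distinct days", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate onsets: no phase transition to fit", call. = FALSE)
  if (any(x <= 0))
    stop("days post-shift must be >= 1", call. = FALSE)
  lx <- log10(x)
  fit <- best_nls(y ~ bottom + (top - bottom) / (1 + 10^((lps - lx) * hill)),
                  data = list(y = y, lx = lx), starts = resync_starts(x, y))
  co <- as.list(stats::coef(fit))
  structure(list(bottom = co$bottom, top = co$top, log_ps50 = co$lps,
                 hill_slope = co$hill, ps50 = 10^co$lps,
                 rss = sum(stats::resid(fit)^2),
                 df = length(y) - 4L, n = length(y),
                 fitted = function(xx)
                   co$bottom + (co$top - co$bottom) /
                     (1 + 10^((co$lps - log10(xx)) * co$hill))),
            class = "resync_fit")
}

# candidate starting values: asymptotes from the extremes of the day range,
# midpoint from the day whose phase is nearest halfway between them, crossed
# with a small grid of slopes and midpoints
resync_starts <- function(x, y) {
  lo <- mean(y[x <= stats::quantile(x, 0.2)])
  hi <- mean(y[x >= stats::quantile(x, 0.8)])
  if (lo == hi) { lo <- min(y); hi <- max(y) }
  mid <- (lo + hi) / 2
  lps0 <- max(log10(x[which.min(abs(y - mid))]), log10(1.1))
  out <- list()
  for (hill in c(1, 3)) for (lps in unique(c(lps0, log10(3))))
    out[[length(out) + 1]] <-
      list(bottom = lo, top = hi, lps = lps, hill = hill)
  out
}

# fit with each start, keep the converged fit with the smallest RSS
best_nls <- function(formula, data, starts) {
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(
      formula, data = data, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(stats::resid(f)^2)
    if (rss < best_rss) { best <- f; best_rss <- rss }
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all starting values",
         call. = FALSE)
  best
}

#' @export
print.resync_fit <- function(x, ...) {
  cat(sprintf(
    "Resynchronization fit: PS50 = %.2f d (Hill %.2f), span %.0f to %.0f min, RSS %.1f on %d df\n",
    x$ps50, x$hill_slope, x$bottom, x$top, x$rss, x$df))
  invisible(x)
}

#' Compare PS50 between two groups by extra sum-of-squares F-test
#'
#' Nested-model comparison of resynchronization speed. Under the default
#' sharing scheme (`"ps50_only"`, the convention of standard dose-response
#' comparison software) the null model shares a single logPS50 across the
#' two groups while Bottom, Top and HillSlope remain group-specific in both
#' models; the alternative frees logPS50 per group. `"all_but_ps50"`
#' instead shares Bottom, Top and HillSlope across groups in both models,
#' which is only appropriate when the groups share their asymptotic phase
#' angles. The statistic is
#' \deqn{F = \frac{(SS_0 - SS_1)/(df_0 - df_1)}{SS_1/df_1}.}
#'
#' @param group_a,group_b `onset_series` objects (or lists with `x`, `y`).
#' @param share `"ps50_only"` (default) or `"all_but_ps50"`.
#' @return list: `F`, `df1`, `df2`, `p`, per-group `ps50`, the two model
#'   RSS values.
#' @export
compare_ps50 <- function(group_a, group_b,
                         share = c("ps50_only", "all_but_ps50")) {
  share <- match.arg(share)
  xy <- function(g) {
    if (inherits(g, "onset_series")) {
      keep <- g$day_post >= 1 & !is.na(g$phase_min)
      list(x = g$day_post[keep], y = g$phase_min[keep])
    } else g
  }
  a <- xy(group_a); b <- xy(group_b)
  x <- c(a$x, b$x); y <- c(a$y, b$y)
  gb <- c(rep(0, length(a$x)), rep(1, length(b$x)))
  lx <- log10(x)
  if (share == "ps50_only") {
    fa <- fit_resync(a$x, a$y); fb <- fit_resync(b$x, b$y)
    ss1 <- fa$rss + fb$rss
    df1 <- fa$df + fb$df       # n - 8
    ps50 <- c(a = fa$ps50, b = fb$ps50)
    starts <- list(list(
      ba = fa$bottom, bb = fb$bottom, ta = fa$top, tb = fb$top,
      ha = fa$hill_slope, hb = fb$hill_slope,
      lps = log10(sqrt(fa$ps50 * fb$ps50))))
    null_fit <- best_nls(
      y ~ (ba + (bb - ba) * gb) +
        ((ta + (tb - ta) * gb) - (ba + (bb - ba) * gb)) /
          (1 + 10^((lps - lx) * (ha + (hb - ha) * gb))),
      data = list(y = y, lx = lx, gb = gb), starts = starts)
    ss0 <- sum(stats::resid(null_fit)^2)
    df0 <- length(y) - 7L
  } else {
    starts <- resync_starts(x, y)
    null_fit <- best_nls(
      y ~ bottom + (top - bottom) / (1 + 10^((lps - lx) * hill)),
      data = list(y = y, lx = lx), starts = starts)
    ss0 <- sum(stats::resid(null_fit)^2)
    df0 <- length(y) - 4L
    alt_fit <- best_nls(
      y ~ bottom + (top - bottom) /
        (1 + 10^(((lpsa + dlps * gb) - lx) * hill)),
      data = list(y = y, lx = lx, gb = gb),
      starts = lapply(starts, function(st)
        list(bottom = st$bottom, top = st$top, lpsa = st$lps, dlps = 0,
             hill = st$hill)))
    ss1 <- sum(stats::resid(alt_fit)^2)
    df1 <- length(y) - 5L
    co <- as.list(stats::coef(alt_fit))
    ps50 <- c(a = 10^co$lpsa, b = 10^(co$lpsa + co$dlps))
  }
  f_stat <- max(((ss0 - ss1) / (df0 - df1)) / (ss1 / df1), 0)
  list(F = f_stat, df1 = df0 - df1, df2 = df1,
       p = stats::pf(f_stat, df0 - df1, df1, lower.tail = FALSE),
       ps50 = ps50, rss_null = ss0, rss_alt = ss1)
}
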