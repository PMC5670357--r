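#' Binned activity series
#'
#' The basic data container: a gapless sequence of non-negative activity
#' counts in equal time bins, anchored to a calendar origin (day index and
#' clock hour of the first bin) and optionally carrying the light schedule
#' under which the record was made. Missing bins are explicit `NA`s, never
#' silently dropped, so bin index always maps linearly to time.
#'
#' @param counts numeric vector of non-negative counts; `NA` marks a missing
#'   bin. Real-valued series are accepted (some analyses operate on
#'   Gaussian-noise series internally).
#' @param bin_width bin width in minutes; must divide 60 evenly.
#' @param start_day 0-based day index of the first bin.
#' @param start_hour clock hour in `[0, 24)` at which the first bin starts.
#' @param schedule optional [light_schedule()] attached to the series.
#' @param allow_negative permit negative values (internal real-valued series
#'   such as zero-mean Gaussian noise; counts written to disk are still
#'   non-negative).
#' @return an object of class `"activity_series"`.
#' @seealso [rebin()], [segment_stage()], [load_activity_csv()]
#' @export
activity_series <- function(counts, bin_width = 5, start_day = 0,
                            start_hour = 0, schedule = NULL,
                            allow_negative = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    stop("empty series", call. = FALSE)
  if (!allow_negative && any(counts < 0, na.rm = TRUE))
    stop("activity counts must be non-negative", call. = FALSE)
  if (bin_width <= 0 || 60 %% bin_width != 0)
    stop("bin_width (minutes) must divide 60 evenly", call. = FALSE)
  if (start_hour < 0 || start_hour >= 24)
    stop("start_hour must lie in [0, 24)", call. = FALSE)
  if (!is.null(schedule) && !inherits(schedule, "light_schedule"))
    stop("schedule must be a light_schedule", call. = FALSE)
  structure(
    list(counts = counts, bin_width = bin_width, start_day = start_day,
         start_hour = start_hour, schedule = schedule),
    class = "activity_series"
  )
}

#' @export
print.activity_series <- function(x, ...) {
  hrs <- length(x$counts) * x$bin_width / 60
  cat(sprintf("Activity series: %d bins of %g min (%.1f days), %.1f%% missing\n",
              length(x$counts), x$bin_width, hrs / 24,
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$counts)

# absolute time (hours since day 0, 00:00) of each bin start
bin_times <- function(series) {
  series$start_day * 24 + series$start_hour +
    (seq_along(series$counts) - 1) * series$bin_width / 60
}

# refuse analyses on windows with too much missing data
check_missing <- function(series, max_frac = 0.1) {
  frac <- mean(is.na(series$counts))
  if (frac > max_frac)
    stop(sprintf("%.1f%% of bins missing exceeds the %.0f%% limit",
                 100 * frac, 100 * max_frac), call. = FALSE)
  invisible(frac)
}

#' Re-bin an activity series to a coarser bin width
#'
#' Counts are summed within each new bin, so total counts are conserved when
#' no bins are missing. A new bin is `NA` if any of its constituent bins is
#' missing. The series length is truncated to a whole number of new bins.
#'
#' @param series an [activity_series()].
#' @param new_width new bin width in minutes; an integer multiple of the
#'   current width.
#' @return an `activity_series` at the new width.
#' @export
rebin <- function(series, new_width) {
  stopifnot(inherits(series, "activity_series"))
  if (new_width %% series$bin_width != 0)
    stop("new_width must be an integer multiple of the current bin width",
         call. = FALSE)
  k <- new_width %/% series$bin_width
  if (k == 1L) return(series)
  n_new <- length(series$counts) %/% k
  if (n_new == 0L) stop("series shorter than one new bin", call. = FALSE)
  m <- matrix(series$counts[seq_len(n_new * k)], nrow = k)
  out <- colSums(m) # NA propagates: a new bin with any missing part is missing
  activity_series(out, bin_width = new_width, start_day = series$start_day,
                  start_hour = series$start_hour, schedule = series$schedule,
                  allow_negative = TRUE)
}

#' Light schedule: LD/DD epochs, shift events and protocol stages
#'
#' Describes the lighting protocol as an ordered set of contiguous epochs
#' (each LD with fixed lights-on/off clock hours, or DD), a list of signed
#' shift events (a jet-lag advance moves lights-on earlier), and named stage
#' bounds used to segment the record (e.g. before-implantation `BI`,
#' post-implantation `PI`, post-jet-lag `P-JL`, and `DD`).
#'
#' A shift of `+s` hours on day `d` advances the cycle: from day `d` on,
#' lights-on and lights-off occur `s` hours earlier (the advance is realized
#' by shortening the preceding dark phase). Delays are negative.
#'
#' @param epochs data frame with columns `start_day` (0-based, ascending),
#'   `regime` (`"LD"` or `"DD"`), `lights_on`, `lights_off` (clock hours;
#'   ignored for DD).
#' @param shifts optional data frame with columns `day`, `hours` (signed;
#'   positive = advance).
#' @param stage_bounds optional named list mapping stage labels to
#'   `c(first_day, last_day)` (inclusive).
#' @return an object of class `"light_schedule"`.
#' @export
light_schedule <- function(epochs, shifts = NULL, stage_bounds = NULL) {
  epochs <- as.data.frame(epochs)
  need <- c("start_day", "regime", "lights_on", "lights_off")
  if (!all(need %in% names(epochs)))
    stop("epochs needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.unsorted(epochs$start_day, strictly = TRUE))
    stop("epoch start days must be strictly increasing", call. = FALSE)
  if (!all(epochs$regime %in% c("LD", "DD")))
    stop("regime must be LD or DD", call. = FALSE)
  if (!is.null(shifts)) {
    shifts <- as.data.frame(shifts)
    if (!all(c("day", "hours") %in% names(shifts)))
      stop("shifts needs columns day, hours", call. = FALSE)
  }
  structure(list(epochs = epochs, shifts = shifts,
                 stage_bounds = stage_bounds),
            class = "light_schedule")
}

# regime and (shift-adjusted) lights-on/off clock hours on a given day
schedule_on_day <- function(schedule, day) {
  ep <- schedule$epochs
  i <- findInterval(day, ep$start_day)
  if (i < 1L) stop("day precedes the first epoch", call. = FALSE)
  on <- ep$lights_on[i]; off <- ep$lights_off[i]
  if (!is.null(schedule$shifts)) {
    applied <- schedule$shifts[schedule$shifts$day <= day, , drop = FALSE]
    if (nrow(applied)) {
      on <- (on - sum(applied$hours)) %% 24
      off <- (off - sum(applied$hours)) %% 24
    }
  }
  list(regime = ep$regime[i], lights_on = on, lights_off = off)
}

#' Zeitgeber time of a clock time point
#'
#' Converts an absolute time to Zeitgeber Time under the attached LD cycle:
#' ZT0 is lights-on and ZT12 is lights-off for a 12:12 cycle. Undefined (an
#' error) during DD epochs, where circadian time referenced to activity onset
#' is the appropriate frame instead.
#'
#' @param t absolute time in hours since day 0, 00:00 (i.e. `day * 24 +
#'   clock_hour`).
#' @param schedule a [light_schedule()].
#' @return ZT in `[0, 24)`.
#' @export
zt_of <- function(t, schedule) {
  day <- floor(t / 24)
  s <- schedule_on_day(schedule, day)
  if (s$regime != "LD")
    stop("ZT is undefined in a DD epoch", call. = FALSE)
  (t %% 24 - s$lights_on) %% 24
}

#' Extract the sub-series for a protocol stage
#'
#' Returns the contiguous sub-series covering the day range registered for
#' `stage` in the schedule's stage bounds (inclusive, half-open bin
#' intervals). The concatenation of all stages reproduces the original series
#' when the bounds tile the record.
#'
#' @param series an [activity_series()] with an attached schedule, or pass
#'   `schedule` explicitly.
#' @param stage stage label present in `schedule$stage_bounds`.
#' @param schedule optional schedule overriding the attached one.
#' @return an `activity_series` for the stage.
#' @export
segment_stage <- function(series, stage, schedule = series$schedule) {
  stopifnot(inherits(series, "activity_series"))
  if (is.null(schedule) || is.null(schedule$stage_bounds[[stage]]))
    stop("unknown stage: ", stage, call. = FALSE)
  b <- schedule$stage_bounds[[stage]]
  t <- bin_times(series)
  keep <- t >= b[1] * 24 & t < (b[2] + 1) * 24
  if (!any(keep)) stop("stage covers no data", call. = FALSE)
  idx <- which(keep)
  t0 <- t[idx[1]]
  activity_series(series$counts[idx], bin_width = series$bin_width,
                  start_day = floor(t0 / 24), start_hour = t0 %% 24,
                  schedule = schedule, allow_negative = TRUE)
}

#' Read an activity series from CSV
#'
#' Expects a header row and two columns: a time column (either a 0-based
#' integer bin index or an ISO-8601 timestamp) and a count column. Gaps in
#' the time column are filled with explicit missing bins and reported via a
#' message; non-monotone times or negative counts are errors.
#'
#' @param path file path.
#' @param bin_width bin width in minutes.
#' @param start_day,start_hour origin used when the time column is an index.
#' @return an [activity_series()].
#' @export
load_activity_csv <- function(path, bin_width = 5, start_day = 0,
                              start_hour = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("need a time column and a count column", call. = FALSE)
  tcol <- df[[1]]; counts <- as.numeric(df[[2]])
  if (any(counts < 0, na.rm = TRUE))
    stop("negative counts in ", path, call. = FALSE)
  if (is.character(tcol)) {
    tt <- as.POSIXct(tcol, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    if (anyNA(tt)) stop("unparseable timestamps in ", path, call. = FALSE)
    idx <- as.numeric(difftime(tt, tt[1], units = "mins")) / bin_width
    origin <- as.POSIXlt(tt[1])
    start_hour <- origin$hour + origin$min / 60 + origin$sec / 3600
  } else {
    idx <- as.numeric(tcol) - tcol[1]
  }
  if (any(idx != round(idx)))
    stop("timestamps are not aligned to the bin width", call. = FALSE)
  idx <- as.integer(round(idx))
  if (is.unsorted(idx, strictly = TRUE))
    stop("non-monotone time column", call. = FALSE)
  full <- rep(NA_real_, max(idx) + 1L)
  full[idx + 1L] <- counts
  n_gap <- sum(is.na(full)) - sum(is.na(counts))
  if (n_gap > 0)
    message(n_gap, " missing bin(s) filled with NA")
  activity_series(full, bin_width = bin_width, start_day = start_day,
                  start_hour = start_hour)
}

#' Write an activity series to CSV
#'
#' Inverse of [load_activity_csv()] for index-based files: writes `bin`
#' (0-based index) and `counts` columns; missing bins are written as empty
#' fields and round-trip back to explicit missing bins.
#'
#' @param series an [activity_series()].
#' @param path output file path.
#' @export
write_activity_csv <- function(series, path) {
  stopifnot(inherits(series, "activity_series"))
  df <- data.frame(bin = seq_along(series$counts) - 1L,
                   counts = series$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
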