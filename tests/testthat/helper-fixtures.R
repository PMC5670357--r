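# deterministic fixtures used across the suite

# hourly two-level day profile repeated m times (perfectly day-repeating)
square_days <- function(m = 10, active = 10, rest = 0, alpha = 12) {
  day <- c(rep(rest, 24 - alpha), rep(active, alpha))
  activity_series(rep(day, m), bin_width = 60)
}

# hourly sinusoid with a given period (hours)
sinusoid_series <- function(n_hours, period = 24, amp = 5, offset = 10) {
  activity_series(offset + amp * sin(2 * pi * seq_len(n_hours) / period),
                  bin_width = 60, allow_negative = TRUE)
}

# evaluate the resynchronization sigmoid at days x (log10-days axis)
sigmoid_points <- function(x, bottom, top, ps50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10(ps50) - log10(x)) * hill))
}
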