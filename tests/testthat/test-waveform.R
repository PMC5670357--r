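test_that("mean waveform folds correctly and flags short windows", {
  s <- square_days(8, active = 10, rest = 2)
  wf <- mean_waveform(s, 24)
  expect_length(wf$activity, 24)
  expect_equal(wf$activity, c(rep(2, 12), rep(10, 12)))
  expect_equal(wf$baseline, 6)
  flat <- activity_series(rep(3, 96), 60)
  expect_equal(mean_waveform(flat, 24)$activity, rep(3, 24))
  expect_error(mean_waveform(activity_series(rep(1, 24), 60), 24),
               "two full periods")
})

test_that("folding at the true period sharpens the waveform", {
  p <- sim_params(tau = 23.92, n_days = 15, seed = 4, rate_rest = 1)
  s <- rebin(simulate_dd(p)$series, 60)
  v_true <- var(mean_waveform(s, 23.92)$activity)
  v_24 <- var(mean_waveform(s, 24)$activity)
  expect_gt(v_true, v_24)
})

test_that("onset detection honors the persistence rule", {
  s <- square_days(8)
  wf <- mean_waveform(s, 24)
  expect_equal(detect_onset(wf), 12)
  # a 1-h supra-baseline blip before the sustained run is rejected
  day <- c(rep(0, 6), 9, rep(0, 5), rep(8, 12))
  wf2 <- mean_waveform(activity_series(rep(day, 4), 60), 24)
  expect_equal(detect_onset(wf2), 12)
  expect_error(detect_onset(mean_waveform(activity_series(rep(2, 96), 60),
                                          24)),
               "cross")
  # noisy square wave: onset within one bin of truth across seeds
  hits <- vapply(1:20, function(sd) {
    set.seed(sd)
    day <- c(rpois(12, 2), rpois(12, 20))
    wfn <- mean_waveform(activity_series(rep(day, 5) + rpois(120, 1), 60),
                         24)
    abs(detect_onset(wfn) - 12) <= 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("onset detection is equivariant under circular rotation", {
  set.seed(8)
  day <- c(rpois(10, 1), rpois(14, 12))
  base <- mean_waveform(activity_series(rep(day, 4), 60), 24)
  o0 <- detect_onset(base)
  for (shift in c(3, 7, 15)) {
    rotated <- mean_waveform(
      activity_series(rep(c(day[-seq_len(shift)], day[seq_len(shift)]), 4),
                      60), 24)
    expect_equal(detect_onset(rotated), (o0 - shift) %% 24)
  }
})

test_that("alpha/rho partition the cycle and split total activity", {
  wf <- mean_waveform(square_days(6, active = 8, rest = 0), 24)
  ar <- alpha_rho(wf)
  expect_equal(ar$alpha, 12)
  expect_equal(ar$rho, 12)
  expect_equal(ar$activity_in_alpha, 1)
  # partition identity on an arbitrary non-constant waveform
  set.seed(5)
  wf2 <- mean_waveform(activity_series(rpois(240, 4) +
                                         rep(c(rep(0, 12), rep(6, 12)), 10),
                                       60), 24)
  ar2 <- alpha_rho(wf2)
  expect_equal(ar2$alpha + ar2$rho, 24)
  below <- sum(wf2$activity[wf2$activity <= wf2$baseline]) /
    sum(wf2$activity)
  expect_equal(ar2$activity_in_alpha + below, 1)
})

test_that("alpha recovery tracks the generator's active-phase duration", {
  alphas <- vapply(1:8, function(s) {
    p <- sim_params(tau = 23.6, alpha_hours = 13.4, n_days = 15,
                    rate_rest = 2, seed = s)
    sim <- simulate_dd(p)
    sb <- suppressWarnings(sokolove_bushell(sim$series))
    wf <- mean_waveform(rebin(sim$series, 60), sb$best_period)
    alpha_rho(wf)$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 13.4), 1)
})

test_that("phase angle follows the sign convention", {
  expect_equal(phase_angle(12), 0)
  expect_equal(phase_angle(10.461), (12 - 10.461) * 60)
  expect_equal(phase_angle(12.25), -15)
  expect_equal(phase_angle(0), 720)
})

test_that("diurnal activity implements the below-baseline rule", {
  wf0 <- mean_waveform(square_days(6, active = 10, rest = 0), 24)
  expect_equal(diurnal_activity(wf0), 0)
  # two-level wave: rest r for 12 h, active a for 12 h -> 100 r / (r + a)
  wf2 <- mean_waveform(square_days(6, active = 8, rest = 3), 24)
  expect_equal(diurnal_activity(wf2), 100 * 3 / (3 + 8))
  expect_error(diurnal_activity(mean_waveform(activity_series(rep(2, 96),
                                                              60), 24)),
               "constant")
  # the lights-on reading is exposed as an alternative rule
  sched <- light_schedule(data.frame(start_day = 0, regime = "LD",
                                     lights_on = 0, lights_off = 12))
  expect_equal(diurnal_activity(wf2, rule = "lights_on", schedule = sched),
               100 * 3 / (3 + 8))
})

test_that("an LD simulation lands in the published diurnal-activity band", {
  pct <- vapply(1:6, function(s) {
    p <- sim_params(n_days = 10, tau = 24, rate_rest = 5, psi_min = 3,
                    masking_gain = 0.7, fragmentation = 0.1, seed = s)
    ld <- simulate_ld(p, lights_on = 8)
    wf <- mean_waveform(rebin(ld$series, 60), 24)
    diurnal_activity(wf)
  }, numeric(1))
  expect_gt(mean(pct), 15)
  expect_lt(mean(pct), 45)
})
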