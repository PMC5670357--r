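test_that("parameter validation rejects impossible configurations", {
  expect_error(sim_params(alpha_hours = 30, tau = 24), "alpha_hours")
  expect_error(sim_params(rate_active = 1, rate_rest = 2), "rate_active")
  expect_error(sim_params(masking_gain = 1.5), "masking_gain")
  expect_error(sim_params(fragmentation = -0.1), "fragmentation")
  expect_error(sim_params(drift_sd = -1), "invalid")
})

test_that("DD simulation is seed-deterministic and occupies the true window", {
  p <- sim_params(tau = 24, n_days = 5, drift_sd = 0, fragmentation = 0,
                  rate_rest = 0, seed = 3)
  a <- simulate_dd(p)
  b <- simulate_dd(p)
  expect_identical(a$series$counts, b$series$counts)
  p2 <- p; p2$seed <- 4L
  expect_false(identical(a$series$counts, simulate_dd(p2)$series$counts))
  # with tau = 24 and rest rate 0, activity sits in a fixed daily window
  m <- matrix(a$series$counts, ncol = 5)
  occupied <- rowSums(m) > 0
  expect_equal(mean(occupied), p$alpha_hours / 24, tolerance = 0.02)
  # the occupancy pattern repeats day after day (day 1 omits the tail of
  # the cycle started before the record; later days are equivalent)
  expect_equal(m[, 2] > 0, m[, 5] > 0)
  # ground truth onsets advance by exactly tau
  expect_equal(diff(a$truth$onset), rep(24, nrow(a$truth) - 1))
})

test_that("jet-lag simulation follows the sigmoid and honors masking", {
  sched <- jetlag_schedule(20, 8)
  p <- sim_params(n_days = 20, tau = 24, resync_ps50 = 3, resync_slope = 2,
                  psi_min = 0, seed = 1)
  sim <- simulate_jetlag(p, sched)
  tr <- sim$truth
  # day 3 post-shift (= PS50) sits exactly halfway between the asymptotes
  mid <- tr$phase_min[tr$day == 8 + 2] # day_post = 3
  expect_equal(mid, (0 + (0 - 360)) / 2, tolerance = 1e-9)
  # pre-shift the onset phase is pinned at psi_min
  expect_equal(tr$phase_min[tr$day < 8], rep(0, 8))
  # masking halves lights-on activity, leaves dark-phase activity alone
  pm <- sim_params(n_days = 6, tau = 24, psi_min = 0, masking_gain = 0.5,
                   rate_rest = 2, seed = 9)
  pu <- pm; pu$masking_gain <- 1
  schm <- jetlag_schedule(6, 4)
  masked <- simulate_jetlag(pm, schm)$series$counts
  unmasked <- simulate_jetlag(pu, schm)$series$counts
  tt <- (seq_along(masked) - 1) * 5 / 60
  lit <- floor(tt / 24) < 4 & tt %% 24 >= 8 & tt %% 24 < 20
  dark <- floor(tt / 24) < 4 & !(tt %% 24 >= 8 & tt %% 24 < 20)
  expect_equal(mean(masked[lit]) / mean(unmasked[lit]), 0.5,
               tolerance = 0.1)
  expect_identical(masked[dark], unmasked[dark])
  # a shift outside the simulated range is an error
  expect_error(simulate_jetlag(sim_params(n_days = 5, seed = 1),
                               jetlag_schedule(20, 8)), "outside")
})

test_that("white-noise generator hits the stated degenerate cases", {
  expect_error(simulate_noise(1), "n > 1")
  s0 <- simulate_noise(100, sd = 0, seed = 1)
  expect_true(all(s0$counts == s0$counts[1]))
  expect_error(intradaily_variability(s0), "variance")
  s1 <- simulate_noise(240, sd = 1, seed = 1)
  expect_identical(s1$counts, simulate_noise(240, sd = 1, seed = 1)$counts)
})

test_that("periodogram recovers the generator period without drift", {
  # parameter-recovery invariant over a batch of seeds
  hits <- vapply(1:20, function(s) {
    p <- sim_params(tau = 23.7, n_days = 12, drift_sd = 0, seed = s)
    sb <- sokolove_bushell(simulate_dd(p)$series)
    abs(sb$best_period - 23.7) <= 5 / 60 + 1e-9
  }, logical(1))
  expect_true(all(hits))
})

test_that("instability knobs move IS, IV and V in the advertised direction", {
  # paired seeds: same randomness, one knob changed
  stats_for <- function(drift, frag, s) {
    p <- sim_params(tau = 23.7, n_days = 15, drift_sd = drift,
                    fragmentation = frag, rate_rest = 2, seed = s)
    sim <- simulate_dd(p)
    h <- rebin(sim$series, 60)
    sb <- suppressWarnings(sokolove_bushell(sim$series))
    v <- variability_index(instant_period(cwt_spectrum(h)))$V
    c(IS = suppressMessages(interdaily_stability(h, sb$best_period)),
      IV = intradaily_variability(h), V = v)
  }
  seeds <- 1:6
  stable <- rowMeans(vapply(seeds, function(s) stats_for(0, 0, s),
                            numeric(3)))
  shaky <- rowMeans(vapply(seeds, function(s) stats_for(0.25, 0.4, s),
                           numeric(3)))
  expect_gt(stable["IS"], shaky["IS"])
  expect_lt(stable["IV"], shaky["IV"])
  expect_gt(stable["V"], shaky["V"])
})
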