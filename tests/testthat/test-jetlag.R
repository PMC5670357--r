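test_that("noiseless sigmoid points are recovered essentially exactly", {
  x <- 1:16
  y <- sigmoid_points(x, bottom = 0, top = 360, ps50 = 3, hill = 1)
  fit <- fit_resync(x, y)
  expect_lt(abs(fit$log_ps50 - log10(3)) / log10(3), 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$top, 360, tolerance = 1e-4)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$df, length(x) - 4L)
  # the fitted curve passes through (PS50, midpoint)
  expect_equal(fit$fitted(fit$ps50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-6)
})

test_that("fit is equivariant under affine maps of the phase axis", {
  x <- rep(1:16, 3)
  set.seed(2)
  y <- sigmoid_points(x, -360, 0, 3.2, 2.5) + rnorm(length(x), 0, 15)
  f1 <- fit_resync(x, y)
  f2 <- fit_resync(x, 2 * y + 100)
  expect_equal(f2$log_ps50, f1$log_ps50, tolerance = 1e-6)
  expect_equal(f2$hill_slope, f1$hill_slope, tolerance = 1e-6)
  expect_equal(f2$bottom, 2 * f1$bottom + 100, tolerance = 1e-4)
  expect_equal(f2$top, 2 * f1$top + 100, tolerance = 1e-4)
})

test_that("PS50 recovery under Gaussian onset noise stays within half a day", {
  errs <- vapply(1:30, function(s) {
    set.seed(s)
    x <- rep(1:16, 6) # 6 animals, 16 days
    y <- sigmoid_points(x, -357, 3, 2.78, 3) + rnorm(length(x), 0, 20)
    abs(fit_resync(x, y)$ps50 - 2.78)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("daily onsets track the generator truth around a shift", {
  sched <- jetlag_schedule(24, 9)
  maes <- vapply(1:5, function(s) {
    p <- sim_params(n_days = 24, tau = 24, rate_rest = 2, psi_min = 10,
                    resync_ps50 = 3, seed = s)
    sim <- simulate_jetlag(p, sched)
    on <- daily_onsets(sim$series, sched)
    # compare on the post-shift axis both tracks share
    cmp <- merge(on[on$day_post >= 1, ], sim$truth, by = "day")
    mean(abs(cmp$phase_min.x - cmp$phase_min.y) / 60, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(maes), 1) # within an hour on average
  # fully entrained days sit at the entrained phase
  p <- sim_params(n_days = 24, tau = 24, rate_rest = 1, psi_min = 0,
                  resync_ps50 = 2, resync_slope = 4, seed = 7)
  sim <- simulate_jetlag(p, sched)
  on <- daily_onsets(sim$series, sched, window = c(2, 23))
  pre <- on$phase_min[on$day_post <= 0]
  expect_true(all(abs(pre - (-360)) <= 60 + 1e-9)) # old phase, new axis
  late <- on$phase_min[on$day_post >= 10]
  expect_true(all(abs(late) <= 60 + 1e-9)) # resynchronized
  expect_error(daily_onsets(sim$series, sched, window = c(10, 20)),
               "straddle")
})

test_that("a detected cohort round-trips its PS50 through the fit", {
  sched <- jetlag_schedule(26, 10)
  onsets <- do.call(rbind, lapply(1:6, function(s) {
    p <- sim_params(n_days = 26, tau = 24, rate_rest = 2, psi_min = 3,
                    fragmentation = 0.1, resync_ps50 = 2.78, seed = s)
    daily_onsets(simulate_jetlag(p, sched)$series, sched)
  }))
  fit <- fit_resync(onsets)
  expect_lt(abs(fit$ps50 - 2.78), 0.75)
})

test_that("the extra sum-of-squares F-test behaves at its extremes", {
  x <- rep(1:16, 6)
  set.seed(4)
  y <- sigmoid_points(x, -357, 3, 3, 3) + rnorm(length(x), 0, 20)
  same <- compare_ps50(list(x = x, y = y), list(x = x, y = y))
  expect_lt(same$F, 1e-6)
  expect_equal(same$p, 1, tolerance = 1e-6)
  # groups at the two emulated resynchronization speeds separate decisively
  set.seed(5)
  ya <- sigmoid_points(x, -357, 3, 2.78, 3) + rnorm(length(x), 0, 20)
  yb <- sigmoid_points(x, -357, 3, 3.96, 3) + rnorm(length(x), 0, 20)
  cmp <- compare_ps50(list(x = x, y = ya), list(x = x, y = yb))
  expect_lt(cmp$p, 0.001)
  expect_equal(unname(cmp$ps50["a"]), 2.78, tolerance = 0.2)
  expect_equal(unname(cmp$ps50["b"]), 3.96, tolerance = 0.2)
})

test_that("the F statistic matches explicit sum-of-squares arithmetic", {
  x <- 1:8
  ya <- sigmoid_points(x, 0, 100, 2.5, 2) + c(1, -1, 2, -2, 1, -1, 2, -2)
  yb <- sigmoid_points(x, 0, 100, 4.5, 2) + c(-1, 1, -2, 2, -1, 1, -2, 2)
  cmp <- compare_ps50(list(x = x, y = ya), list(x = x, y = yb),
                      share = "all_but_ps50")
  df0 <- 16 - 4; df1 <- 16 - 5
  f_hand <- ((cmp$rss_null - cmp$rss_alt) / (df0 - df1)) /
    (cmp$rss_alt / df1)
  expect_equal(cmp$F, f_hand)
  expect_equal(cmp$df1, df0 - df1)
  expect_equal(cmp$df2, df1)
  expect_equal(cmp$p, pf(f_hand, df0 - df1, df1, lower.tail = FALSE))
})

test_that("degenerate onset sets are refused", {
  expect_error(fit_resync(1:4, c(1, 2, 3, 4)), "5 distinct")
  expect_error(fit_resync(1:10, rep(5, 10)), "degenerate")
})
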