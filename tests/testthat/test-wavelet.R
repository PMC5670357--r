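test_that("a pure 24-h sinusoid rides at 24 h across interior times", {
  s <- sinusoid_series(15 * 24)
  sp <- cwt_spectrum(s)
  tr <- instant_period(sp)
  interior <- tr$valid & tr$times > 48 & tr$times < max(tr$times) - 48
  expect_gt(mean(interior), 0.5)
  expect_true(all(abs(tr$period[interior] - 24) < 1))
  # a constant offset does not move the ridge
  s2 <- sinusoid_series(15 * 24, offset = 50)
  tr2 <- instant_period(cwt_spectrum(s2))
  expect_equal(tr2$period[interior], tr$period[interior], tolerance = 1e-9)
})

test_that("significance behaves like a level-alpha test on white noise", {
  fp <- vapply(1:6, function(s) {
    ns <- simulate_noise(360, sd = 1, seed = 100 + s)
    sp <- cwt_spectrum(ns)
    mask <- significance_mask(sp, 0.05)
    inside <- outer(sp$periods, sp$coi, "<=")
    sum(mask & inside) / sum(inside)
  }, numeric(1))
  # pointwise rate near the nominal level (wavelet cells are correlated,
  # so allow generous sampling slack around 0.05)
  expect_lt(mean(fp), 0.15)
  # level 1 marks everything inside the cone of influence
  ns <- simulate_noise(360, sd = 1, seed = 1)
  sp <- cwt_spectrum(ns)
  m1 <- significance_mask(sp, 1 - 1e-12)
  inside <- outer(sp$periods, sp$coi, "<=")
  expect_true(all(m1[inside]))
  expect_false(any(m1[!inside]))
})

test_that("a strong rhythm is significant throughout its ridge band", {
  s <- sinusoid_series(15 * 24, amp = 8)
  sp <- cwt_spectrum(s)
  tr <- instant_period(sp)
  interior <- tr$times > 48 & tr$times < max(tr$times) - 48
  expect_true(all(tr$valid[interior]))
})

test_that("a chirp yields a monotone-trending period track", {
  n <- 15 * 24
  inst <- seq(23, 25, length.out = n)
  phase <- cumsum(2 * pi / inst)
  s <- activity_series(10 + 5 * sin(phase), 60, allow_negative = TRUE)
  tr <- instant_period(cwt_spectrum(s))
  interior <- tr$valid & tr$times > 48 & tr$times < max(tr$times) - 48
  expect_gt(cor(tr$times[interior], tr$period[interior],
                method = "spearman"), 0.9)
})

test_that("shannon entropy matches direct evaluation", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log(7))
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "negative")
})

test_that("V spans its [0, 1] range at the stated extremes", {
  expect_equal(variability_index(rep(24, 100), bin_width = 0.1)$V, 1)
  spread <- variability_index(seq_len(100), bin_width = 0.5)
  expect_equal(spread$V, 0, tolerance = 1e-12)
  expect_equal(spread$SE, log(100))
  # intermediate: probabilities (0.5, 0.25, 0.25) over N = 4
  v4 <- variability_index(c(20, 20.05, 21, 22), bin_width = 0.5)
  expect_equal(v4$V, 1 - 1.5 * log(2) / log(4))
  expect_error(variability_index(24, bin_width = 0.1), "at least 2")
})

test_that("V is permutation-invariant and decreases with spread", {
  # relabeling histogram bins leaves V unchanged
  a <- variability_index(rep(c(21, 23, 27), times = c(6, 2, 4)),
                         bin_width = 0.5)$V
  b <- variability_index(rep(c(27, 21, 23), times = c(6, 2, 4)),
                         bin_width = 0.5)$V
  expect_equal(a, b)
  # for fixed N, occupying more equiprobable bins strictly lowers V
  N <- 24
  vs <- vapply(c(1, 2, 4, 8, 24), function(k) {
    periods <- rep(seq(20, by = 1, length.out = k), each = N / k)
    variability_index(periods, bin_width = 0.5)$V
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
})
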