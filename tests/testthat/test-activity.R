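test_that("activity series validates its invariants", {
  expect_error(activity_series(c(1, -2, 3), 60), "non-negative")
  expect_error(activity_series(1:10, bin_width = 7), "divide 60")
  expect_error(activity_series(numeric(0)), "empty")
  s <- activity_series(rep(1, 288), bin_width = 5)
  expect_s3_class(s, "activity_series")
  expect_length(s$counts, 288)
})

test_that("rebin sums counts and conserves totals", {
  s <- activity_series(rep(1, 288), bin_width = 5)
  h <- rebin(s, 60)
  expect_equal(h$counts, rep(12, 24))
  expect_identical(rebin(s, 5), s)
  expect_error(rebin(s, 7), "multiple")
  set.seed(42)
  r <- activity_series(rpois(1440, 3), bin_width = 5)
  expect_equal(sum(rebin(r, 30)$counts), sum(r$counts))
  # missingness propagates instead of vanishing
  r$counts[5] <- NA
  expect_true(is.na(rebin(r, 30)$counts[1]))
})

test_that("ZT conversion anchors to lights-on and is undefined in DD", {
  sched <- light_schedule(
    data.frame(start_day = 0, regime = "LD", lights_on = 8, lights_off = 20),
    shifts = data.frame(day = 10, hours = 6))
  expect_equal(zt_of(8, sched), 0)
  expect_equal(zt_of(20, sched), 12)   # lights-off is ZT12
  expect_equal(zt_of(2, sched), 18)
  # after a 6-h advance lights-on moves to 02:00 and ZT0 follows it
  expect_equal(zt_of(10 * 24 + 2, sched), 0)
  expect_equal(zt_of(10 * 24 + 14, sched), 12)
  dd <- light_schedule(data.frame(start_day = 0, regime = "DD",
                                  lights_on = NA, lights_off = NA))
  expect_error(zt_of(8, dd), "DD")
})

test_that("stage segmentation tiles the record", {
  sched <- light_schedule(
    data.frame(start_day = 0, regime = "LD", lights_on = 8, lights_off = 20),
    stage_bounds = list(BI = c(0, 24), PI = c(25, 39)))
  s <- activity_series(seq_len(40 * 288), bin_width = 5, schedule = sched)
  bi <- segment_stage(s, "BI")
  pi_ <- segment_stage(s, "PI")
  expect_length(bi$counts, 25 * 288)
  expect_length(pi_$counts, 15 * 288)
  expect_equal(c(bi$counts, pi_$counts), s$counts)
  expect_equal(pi_$start_day, 25)
  expect_error(segment_stage(s, "DD"), "unknown stage")
})

test_that("CSV round trip preserves the series and flags gaps", {
  tmp <- tempfile(fileext = ".csv")
  set.seed(7)
  s <- activity_series(rpois(288, 4), bin_width = 5)
  write_activity_csv(s, tmp)
  s2 <- load_activity_csv(tmp, bin_width = 5)
  expect_equal(s2$counts, s$counts)
  # drop one row: the gap must come back as an explicit missing bin
  df <- read.csv(tmp)
  write.csv(df[-10, ], tmp, row.names = FALSE)
  expect_message(s3 <- load_activity_csv(tmp, bin_width = 5), "missing")
  expect_length(s3$counts, 288)
  expect_true(is.na(s3$counts[10]))
  # negative counts rejected
  df$counts[1] <- -1
  write.csv(df, tmp, row.names = FALSE)
  expect_error(load_activity_csv(tmp, bin_width = 5), "negative")
})

test_that("analyses refuse windows with too much missing data", {
  x <- rep(5, 240)
  x[1:30] <- NA
  s <- activity_series(x, bin_width = 60)
  expect_error(intradaily_variability(s), "missing")
})
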