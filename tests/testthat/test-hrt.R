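grid_train <- function(times, t0, n, kind = "r_peak", sigma = 1.25,
                       rate = 125) {
  encode_train(peak_train(times, kind = kind), t0, rate, n, sigma)
}

test_that("cross-correlation peaks at zero lag for identical trains", {
  ev <- c(100, 900, 1700, 2500)
  a <- grid_train(ev, 0, 351, "pulse_arrival")
  b <- grid_train(ev, 0, 351)
  xc <- cross_correlate_trains(a, b)
  expect_equal(xc$lags_ms[which.max(xc$cc)], 0)
  expect_equal(max(xc$cc), 1, tolerance = 1e-12)
})

test_that("an ECG pattern earlier by delta puts the argmax at -delta", {
  ev <- c(500, 1300, 2100, 2900)
  delta <- 15 * 8  # 15 grid samples
  oct_enc <- grid_train(ev, 0, 426, "pulse_arrival")
  ecg_enc <- grid_train(ev - delta, -2000, 800)
  xc <- cross_correlate_trains(oct_enc, ecg_enc)
  expect_equal(xc$lags_ms[which.max(xc$cc)], -delta)
})

test_that("interleaved trains correlate weakly", {
  a <- grid_train(seq(100, 3000, by = 400), 0, 400, "pulse_arrival",
                  sigma = 0.6)
  b <- grid_train(seq(300, 3200, by = 400) - 96, -1000, 600, sigma = 0.6)
  # restrict attention to small lags: within half a period the events stay
  # interleaved, so no alignment reaches half of a perfect match
  xc <- cross_correlate_trains(a, b)
  near <- abs(xc$lags_ms + 96) <= 100
  expect_lt(max(xc$cc[near]), 0.5)
})

test_that("degenerate and mismatched trains are rejected", {
  a <- grid_train(c(100, 500), 0, 100, "pulse_arrival")
  z <- encode_train(peak_train(numeric(0)), -496, 125, 300, 1.25)
  expect_error(cross_correlate_trains(a, z), "all-zero")
  b <- encode_train(peak_train(c(100, 500)), -500, 100, 300, 1.25)
  expect_error(cross_correlate_trains(a, b), "rate")
})

test_that("HRT is the additive inverse of the within-cycle argmax", {
  set.seed(2)
  r <- cumsum(c(200, 850 + runif(12, -20, 20)))
  arr <- r[3:10] + 144
  est <- estimate_hrt(peak_train(arr, "pulse_arrival"), peak_train(r))
  expect_equal(est$hrt_ms, -est$offset_ms)
  expect_lt(abs(est$hrt_ms - 144), 8)  # one grid bin
  expect_false(est$is_outlier)
})

test_that("coincident trains give HRT 0 and no outlier flag", {
  r <- seq(200, 8000, by = 820)
  est <- estimate_hrt(peak_train(r[3:8], "pulse_arrival"), peak_train(r))
  expect_equal(est$hrt_ms, 0)
  expect_false(est$is_outlier)
})

test_that("delays beyond one cardiac cycle are flagged as outliers", {
  set.seed(5)
  r <- cumsum(c(200, 850 + runif(14, -25, 25)))
  rr <- mean(diff(r))
  arr <- (r + 1.5 * rr)
  arr <- arr[arr < max(r) - 500][3:9]
  est <- estimate_hrt(peak_train(arr, "pulse_arrival"), peak_train(r))
  expect_true(est$is_outlier)
  # the within-cycle estimate still lies in [0, rr]
  expect_gte(est$hrt_ms, 0)
  expect_lte(est$hrt_ms, est$rr_mean_ms)
})

test_that("shifting all arrivals shifts the HRT by the same amount", {
  set.seed(8)
  r <- cumsum(c(150, 840 + runif(12, -20, 20)))
  arr <- r[3:10] + 120
  base <- estimate_hrt(peak_train(arr, "pulse_arrival"), peak_train(r))
  delta <- 48  # 6 grid bins
  shifted <- estimate_hrt(peak_train(arr + delta, "pulse_arrival"),
                          peak_train(r))
  expect_equal(shifted$hrt_ms, base$hrt_ms + delta, tolerance = 8)
})

test_that("correlation is invariant to positive scaling of either train", {
  ev <- c(300, 1100, 1900)
  a <- grid_train(ev, 0, 300, "pulse_arrival")
  b <- grid_train(ev - 200, -1496, 600)
  x1 <- cross_correlate_trains(a, b)
  a$signal$values <- 3.7 * a$signal$values
  x2 <- cross_correlate_trains(a, b)
  expect_equal(x1$cc, x2$cc, tolerance = 1e-12)
})

test_that("the coefficient of variation matches hand computations", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 0.5)
  expect_equal(cv(c(100, 100, 120)), sd(c(100, 100, 120)) / mean(c(100, 100, 120)))
  expect_equal(cv(c(100, 100, 120)), 0.10825, tolerance = 1e-4)
  expect_equal(cv(2.5 * c(1, 2, 3)), cv(c(1, 2, 3)), tolerance = 1e-12)
  expect_error(cv(7), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("the CoV report aggregates the four reproducibility groupings", {
  rec <- cohort_records(
    subject_id = rep(c("S1", "S2"), each = 4),
    exam_id = rep(c("E1", "E1", "E2", "E2"), 2),
    vessel_id = rep(c("A1", "A2"), 4),
    hrt_ms = c(100, 100, 100, 100, 120, 120, 120, 120))
  rep1 <- cov_report(rec)
  expect_equal(rep1$inter_subject_cov, cv(c(100, 120)))
  expect_equal(rep1$inter_subject_cov, 0.1286, tolerance = 1e-3)
  expect_equal(rep1$intra_subject_cov_mean, 0)
  expect_equal(rep1$intra_exam_cov_mean, 0)
  expect_equal(rep1$intra_vessel_cov_mean, 0)

  # constant cohort: every available CoV is zero
  rec0 <- cohort_records("S1", c("E1", "E2"), "A1", c(140, 140))
  rep0 <- cov_report(rec0)
  expect_true(is.na(rep0$inter_subject_cov))  # single subject
  expect_equal(rep0$intra_subject_cov_mean, 0)

  # outliers are excluded before any statistic
  rec2 <- cohort_records(c("S1", "S1", "S2"), c("E1", "E2", "E1"),
                         "A1", c(100, 5000, 100), c(FALSE, TRUE, FALSE))
  rep2 <- cov_report(rec2)
  expect_identical(rep2$n_outliers_excluded, 1L)
  expect_equal(rep2$overall_mean_ms, 100)
})
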