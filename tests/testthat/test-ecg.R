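test_that("resampling interpolates linearly and never extrapolates", {
  # constant trace: any jittered timestamps give the constant back
  tr <- ecg_trace(c(0, 7900, 16300, 23800, 32100), rep(3.5, 5))
  rs <- resample_ecg(tr, 125)
  expect_true(all(abs(rs$values - 3.5) < 1e-12))

  # linear ramp is reproduced exactly
  t_us <- sort(c(0, 5000, 9000, 17000, 24000, 33000))
  tr <- ecg_trace(t_us, t_us / 1000)
  rs <- resample_ecg(tr, 125)
  expect_equal(rs$values, signal_times_ms(rs), tolerance = 1e-12)

  # hand-derived two-point case: samples at 0, 8, 16 ms -> 0, 0.5, 1
  tr <- ecg_trace(c(0, 16000), c(0, 1))
  rs <- resample_ecg(tr, 125)
  expect_equal(length(rs$values), 3L)
  expect_equal(rs$values, c(0, 0.5, 1))
  expect_equal(signal_times_ms(rs), c(0, 8, 16))

  # grid stays inside the trace span
  tr <- ecg_trace(c(0, 9000, 19500), c(1, 2, 3))
  rs <- resample_ecg(tr, 125)
  expect_lte(max(signal_times_ms(rs)), 19.5)
  expect_false(anyNA(rs$values))
})

test_that("resampling an already-uniform signal at its own rate is identity", {
  set.seed(7)
  vals <- rnorm(200)
  tr <- ecg_trace(seq(0, by = 8000, length.out = 200), vals)
  rs <- resample_ecg(tr, 125)
  expect_equal(rs$values, vals, tolerance = 1e-12)
})

test_that("trace validation rejects bad input and collapses duplicates", {
  expect_error(ecg_trace(1000, 1), "at least 2")
  expect_error(ecg_trace(c(0, 5, 3), c(1, 2, 3)), "non-decreasing")
  # duplicate timestamps collapse to their mean value
  tr <- ecg_trace(c(0, 8000, 8000, 16000), c(0, 2, 4, 1))
  expect_equal(tr$values, c(0, 3, 1))
  expect_error(ecg_trace(c(0, 8000), c(1, NaN)), "finite")
})

test_that("clock offset places the trace on the OCT clock", {
  tr0 <- ecg_trace(c(0, 8000, 16000), c(1, 2, 3))
  tr1 <- ecg_trace(c(0, 8000, 16000), c(1, 2, 3), clock_offset_ms = 250)
  expect_equal(resample_ecg(tr0)$t0_ms + 250, resample_ecg(tr1)$t0_ms)
})

test_that("mean RR interval is the mean successive difference", {
  expect_equal(mean_rr_ms(peak_train(c(0, 1000, 2000))), 1000)
  expect_equal(mean_rr_ms(peak_train(c(0, 900, 2100))), 1050)
  expect_error(mean_rr_ms(peak_train(500)), "at least 2")
})

test_that("train encoding rasterizes, smooths and normalises", {
  # single event on a grid point: symmetric bump, max exactly 1 there
  enc <- encode_train(peak_train(80), t0_ms = 0, rate_hz = 125,
                      n_samples = 21, sigma_samples = 1.25)
  v <- enc$signal$values
  expect_identical(which.max(v), 11L)
  expect_identical(max(v), 1)
  expect_equal(v[11 + 1:5], v[11 - 1:5], tolerance = 1e-12)

  # empty train encodes to zeros
  enc0 <- encode_train(peak_train(numeric(0)), 0, 125, 15, 1.25)
  expect_true(all(enc0$signal$values == 0))

  # two events 3 samples apart: equal values at the event samples, 2 maxima
  enc2 <- encode_train(peak_train(c(40, 64)), 0, 125, 14, 1.25)
  v2 <- enc2$signal$values
  expect_equal(v2[6], v2[9], tolerance = 1e-12)
  expect_equal(v2, encode_oracle(c(6L, 9L), 14L, 1.25), tolerance = 1e-12)
  interior <- which(diff(sign(diff(v2))) == -2) + 1L
  expect_identical(length(interior), 2L)

  # tie rounds toward the earlier sample: event exactly between samples 5,6
  enc_t <- encode_train(peak_train(36), 0, 125, 11, 1.25)
  expect_identical(which.max(enc_t$signal$values), 5L)
})

test_that("encoded values stay in [0,1] with max 1 whenever events exist", {
  set.seed(11)
  for (k in 1:20) {
    times <- sort(runif(sample(1:6, 1), 0, 800))
    enc <- encode_train(peak_train(times), 0, 125, 101, runif(1, 0.5, 3))
    v <- enc$signal$values
    expect_gte(min(v), 0)
    expect_identical(max(v), 1)
  }
})

test_that("trains serialize to the documented JSON shapes", {
  pt <- peak_train(c(10, 500, 900))
  doc <- jsonlite::fromJSON(train_to_json(pt))
  expect_identical(doc$kind, "r_peak")
  expect_equal(doc$times_ms, c(10, 500, 900))
  enc <- encode_train(pt, 0, 125, 120, 1.25)
  doc2 <- jsonlite::fromJSON(train_to_json(enc))
  expect_equal(doc2$rate_hz, 125)
  expect_equal(length(doc2$values), 120L)
})

test_that("ECG CSV round trip preserves the trace", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tr <- ecg_trace(seq(0, by = 8000, length.out = 50), rnorm(50))
  write_ecg_csv(tr, tmp)
  back <- read_ecg_csv(tmp)
  expect_equal(back$times_us, tr$times_us)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
  # missing columns are rejected
  writeLines(c("a,b", "1,2"), tmp)
  expect_error(read_ecg_csv(tmp), "timestamp_us")
})
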