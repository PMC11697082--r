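test_that("the display transform is 255 * I^(1/4) and rank-preserving", {
  expect_equal(visualization_transform(0), 0)
  expect_equal(visualization_transform(1), 255)
  expect_equal(visualization_transform(0.0625), 127.5)
  expect_equal(visualization_transform(0.5), 255 * 0.5^0.25)
  x <- seq(0, 1, length.out = 101)
  expect_true(all(diff(visualization_transform(x)) > 0))
  expect_error(visualization_transform(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("the registration reference is the mean of the leading frames", {
  st <- make_const_stack(rep(0.4, 12))
  expect_true(all(abs(build_reference(st, 10) - 0.4) < 1e-12))
  st2 <- make_const_stack(seq(0.1, 1, by = 0.1))
  expect_true(all(abs(build_reference(st2, 10) - 0.55) < 1e-12))
  expect_true(all(build_reference(st2, 1) == 0.1))
  expect_error(build_reference(st2, 11), "between 1 and")
})

test_that("the 7x7 subarea spans about 20 x 27 um at the clinical raster", {
  sz <- subarea_size_um(scan_params())
  expect_equal(unname(sz[1]), 7 * 2.9 / 1024 * 1000, tolerance = 1e-12)
  expect_lt(abs(sz[1] - 20), 1)
  expect_lt(abs(sz[2] - 27), 1)
})

test_that("subarea SNR follows the quality-score noise model", {
  # uniform frame at c with Q = 10 dB: snr = c * max_raw / (max_raw/10) = 10c
  st <- make_const_stack(c(0.2, 0.2), q_db = 10)
  tr <- vessel_track(cbind(c(10, 10), c(10, 10)), "A1", 3)
  ser <- extract_subarea_series(st, tr)
  expect_equal(ser$snr, c(2, 2), tolerance = 1e-12)
  # identical frames: mean equals the pixel peak, so snr_drop is exactly 1
  expect_equal(ser$snr_drop, c(1, 1))
})

test_that("the SNR drop is invariant to how the raw data were normalised", {
  # representing the same raw image with intensities scaled by s and the
  # stored maximum scaled by 1/s rescales every per-frame SNR by the same
  # factor, so the reference-normalised drop is unchanged
  set.seed(4)
  sp <- scan_params(width_px = 32L, height_px = 24L,
                    fov_lateral_mm = 1, fov_axial_mm = 1)
  f <- matrix(runif(24 * 32, 0.1, 0.9), 24, 32)
  mk <- function(scale) bscan_stack(
    list(pmin(f * scale, 1), pmin(f * 0.8 * scale, 1)),
    c(0, 50), max_raw = c(1000, 1000) / scale, quality_db = c(20, 20),
    params = sp, registered = TRUE)
  tr <- vessel_track(cbind(c(12, 12), c(10, 10)), "A1", 3)
  s1 <- extract_subarea_series(mk(1), tr)
  s2 <- extract_subarea_series(mk(0.5), tr)
  expect_equal(s2$snr, 0.5 * s1$snr, tolerance = 1e-12)
  expect_equal(s1$snr_drop, s2$snr_drop, tolerance = 1e-12)
})

test_that("snr_drop lies in (0,1] and windows must stay inside the image", {
  cfg <- sim_config(seed = 12, oct_noise_sd = 1e-3, jitter_px = 0,
                    duration_s = 2)
  ex <- generate_exam(cfg)
  st <- ex$stack; st$registered <- TRUE
  ser <- extract_subarea_series(st, ex$tracks[[1]])
  expect_true(all(ser$snr_drop > 0 & ser$snr_drop <= 1))
  n <- length(st$frames)
  border <- vessel_track(cbind(rep(1L, n), rep(10L, n)), "bad", 3)
  expect_error(extract_subarea_series(st, border), "border")
  expect_error(extract_subarea_series(ex$stack, ex$tracks[[1]]), "registered")
})

test_that("the generator's designed drop sequence is recovered noise-free", {
  cfg <- sim_config(seed = 5, oct_noise_sd = 0, jitter_px = 0, duration_s = 4)
  ex <- generate_exam(cfg)
  st <- ex$stack; st$registered <- TRUE
  ser <- extract_subarea_series(st, ex$tracks[[1]])
  rel <- abs(ser$snr_drop - ex$truth$snr_drop_true) / ex$truth$snr_drop_true
  expect_lt(max(rel), 0.02)
})

test_that("the stack container round-trips through disk", {
  cfg <- sim_config(seed = 9, duration_s = 1)
  ex <- generate_exam(cfg)
  dir <- withr::local_tempdir()
  write_stack(ex$stack, dir)
  back <- read_stack(dir)
  expect_identical(length(back$frames), length(ex$stack$frames))
  expect_equal(back$timestamps_ms, ex$stack$timestamps_ms)
  expect_equal(back$quality_db, ex$stack$quality_db)
  expect_lt(max(abs(back$frames[[3]] - ex$stack$frames[[3]])), 1e-6)
  expect_identical(back$params$width_px, ex$stack$params$width_px)
  # corrupt size is caught
  writeBin(raw(16), file.path(dir, "frames.bin"))
  expect_error(read_stack(dir), "size")
})

test_that("annotations round-trip and are validated against the stack", {
  cfg <- sim_config(seed = 9, duration_s = 1, n_vessels = 2L)
  ex <- generate_exam(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ex$tracks, path)
  back <- read_annotations(path)
  expect_setequal(names(back), c("A1", "A2"))
  expect_equal(back$A1$centers_px, ex$tracks[[1]]$centers_px)
  # a track of the wrong length cannot be applied to the stack
  st <- ex$stack; st$registered <- TRUE
  short <- vessel_track(cbind(20L, 20L), "A1", 3)
  expect_error(extract_subarea_series(st, short), "length")
})
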