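test_that("the forward washout relation matches its closed forms", {
  wp <- washout_params()
  expect_identical(forward_washout(0, wp), 1)
  # first null of sinc at dz = lambda/2
  v1 <- (pi) / (wp$k0 * wp$n * wp$t) * 1000
  expect_lt(forward_washout(v1, wp), 1e-25)
  # quarter-wavelength displacement: drop = (2/pi)^2, v = lambda/(4 n t)
  v2 <- wp$wavelength_m / (4 * wp$n * wp$t) * 1000
  expect_equal(forward_washout(v2, wp), (2 / pi)^2, tolerance = 1e-12)
  expect_equal(v2, 3.610819, tolerance = 1e-6)
  expect_error(forward_washout(-1, wp), "non-negative")
})

test_that("inversion finds the principal-lobe root to high accuracy", {
  wp <- washout_params()
  expect_equal(invert_washout(1, wp), data.frame(nsi = 0L, v = 0))
  s <- invert_washout((2 / pi)^2, wp)
  expect_equal(s$v[1], wp$wavelength_m / (4 * wp$n * wp$t) * 1000,
               tolerance = 1e-9)
  # independent grid-scan oracle at drop = 0.5
  s5 <- invert_washout(0.5, wp)
  x5 <- s5$v[1] / 1000 * wp$k0 * wp$n * wp$t
  expect_equal(x5, grid_scan_root(0.5), tolerance = 1e-5)
  expect_equal(x5, 1.39156, tolerance = 1e-4)
  expect_error(invert_washout(0, wp), "\\(0, 1\\]")
  expect_error(invert_washout(1.2, wp), "\\(0, 1\\]")
})

test_that("forward and inverse washout are mutually inverse", {
  for (it in c(44.8e-6, 11.2e-6)) {
    wp <- washout_params(integration_time_s = it)
    drops <- seq(0.01, 1, length.out = 400)
    back <- vapply(drops, function(d)
      forward_washout(invert_washout(d, wp)$v[1], wp), numeric(1))
    expect_lt(max(abs(back - drops)), 1e-9)
    # velocity round trip inside the principal lobe
    vs <- seq(0, 0.95 * pi, length.out = 50) / (wp$k0 * wp$n * wp$t) * 1000
    vb <- vapply(vs, function(v)
      invert_washout(forward_washout(v, wp), wp)$v[1], numeric(1))
    expect_lt(max(abs(vb - vs) / pmax(vs, 1e-9)), 1e-9)
  }
})

test_that("side-lobe branches increase with NSI and shrink with the drop", {
  wp <- washout_params(n_branches = 6L)
  s <- invert_washout(0.01, wp)
  expect_gt(nrow(s), 2)
  expect_identical(s$nsi, seq_len(nrow(s)) - 1L)
  expect_true(all(diff(s$v) > 0))
  # every solution reproduces the drop
  expect_true(all(abs(forward_washout(s$v, wp) - 0.01) < 1e-9))
  # branch count is non-increasing in the drop
  counts <- vapply(c(0.005, 0.02, 0.05, 0.2, 0.6, 1), function(d)
    nrow(invert_washout(d, wp)), integer(1))
  expect_true(all(diff(counts) <= 0))
  # both-flank mode returns two roots per open side lobe
  s2 <- invert_washout(0.01, wp, branch_mode = "both")
  expect_identical(nrow(s2), 2L * (nrow(s) - 1L) + 1L)
})

test_that("halving the integration time exactly doubles every solution", {
  wp1 <- washout_params(integration_time_s = 44.8e-6)
  wp2 <- washout_params(integration_time_s = 22.4e-6)
  for (d in c(0.03, 0.3, 0.9)) {
    r <- invert_washout(d, wp2)$v / invert_washout(d, wp1)$v
    expect_equal(r, rep(2, length(r)), tolerance = 1e-9)
  }
})

test_that("flow profiles carry the envelope and its timestamp gradient", {
  wp <- washout_params()
  mk_series <- function(drops, t_ms) structure(
    list(snr_drop = drops, snr = drops, reference_snr = 1,
         mean_intensity = drops, timestamps_ms = t_ms, vessel_id = "A1"),
    class = "subarea_series")
  # constant drop: flat envelope, zero gradient
  fp <- build_flow_profile(mk_series(rep(0.4, 6), seq(0, 250, by = 50)), wp)
  expect_equal(diff(fp$profile$envelope_v), rep(0, 5))
  expect_equal(fp$profile$gradient, rep(0, 6))
  # velocity linear in time (within the principal lobe): constant gradient,
  # exact for central differences on the uneven timestamps used here
  t_ms <- c(0, 40, 90, 150, 200, 260)
  v_lin <- 1 + 0.004 * t_ms
  fp2 <- build_flow_profile(mk_series(forward_washout(v_lin, wp), t_ms),
                            washout_params(n_branches = 1L))
  expect_equal(fp2$profile$envelope_v, v_lin, tolerance = 1e-9)
  expect_equal(fp2$profile$gradient, rep(0.004, 6), tolerance = 1e-7)
  expect_error(build_flow_profile(mk_series(c(0.5, 1.2), c(0, 50)), wp),
               "clip upstream")
})

test_that("pulse arrivals are the per-bin sharpest rises", {
  # sawtooth pulses: sharp one-frame rise, slow decay
  period <- 400; fi <- 50
  t_ms <- seq(0, 2395, by = fi)
  phase <- (t_ms %% period) / period
  env <- ifelse(phase < fi / period, 5 + 20 * phase * period / fi,
                25 - 18 * phase)
  prof <- structure(list(timestamps_ms = t_ms, envelope_v = env,
                         gradient = c(diff(env) / diff(t_ms), 0),
                         vessel_id = "A1"), class = "flow_profile")
  arr <- detect_pulse_arrivals(prof, period)
  rises <- seq(0, max(t_ms), by = period)
  rises <- rises[rises <= max(t_ms) - 0]
  for (r in rises[seq_along(arr$times_ms)])
    expect_lte(min(abs(arr$times_ms - r)), fi)
  # at most one event per bin, strictly increasing
  expect_true(all(diff(arr$times_ms) > 0))
  expect_lte(length(arr$times_ms), ceiling(diff(range(t_ms)) / period) + 1)

  # constant-slope profile in a single bin: one event, tie -> earliest frame
  prof2 <- structure(list(timestamps_ms = c(0, 50, 100, 150),
                          envelope_v = c(1, 2, 3, 4),
                          gradient = rep(0.02, 4), vessel_id = "A1"),
                     class = "flow_profile")
  arr2 <- detect_pulse_arrivals(prof2, 1000)
  expect_identical(arr2$times_ms, 0)
  expect_error(detect_pulse_arrivals(prof2, -5), "positive")
})
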