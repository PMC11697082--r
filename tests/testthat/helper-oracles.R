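# Independent oracles and small fixture builders used across the test files.

# Naive R-peak detector, independent of the Engelse-Zeelenberg path:
# amplitude threshold at half the maximum deviation from the median plus a
# refractory period, peak refined by local argmax.
naive_r_peaks <- function(signal, refractory_s = 0.3) {
  y <- signal$values - stats::median(signal$values)
  thr <- 0.5 * max(y)
  above <- which(y > thr)
  if (!length(above)) return(numeric(0))
  gaps <- c(Inf, diff(above))
  starts <- above[gaps > refractory_s * signal$rate_hz]
  peaks <- vapply(starts, function(s) {
    win <- s:min(length(y), s + round(0.15 * signal$rate_hz))
    win[which.max(y[win])]
  }, numeric(1))
  signal$t0_ms + (peaks - 1) * 1000 / signal$rate_hz
}

# fraction of true events matched by a detection within tol_ms
match_fraction <- function(detected, truth, tol_ms) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(tt)
    length(detected) > 0 && min(abs(detected - tt)) <= tol_ms, logical(1)))
}

# direct O(n^2) convolution + normalisation oracle for encode_train
encode_oracle <- function(event_idx, n, sigma) {
  x <- numeric(n)
  for (i in event_idx) x[i] <- x[i] + 1
  half <- max(1L, floor(4 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_along(kern)) {
      src <- i - (j - half - 1L)
      if (src >= 1L && src <= n) acc <- acc + kern[j] * x[src]
    }
    y[i] <- acc
  }
  if (max(y) > 0) y / max(y) else y
}

# brute-force grid-scan inversion of sinc^2 on the principal lobe
grid_scan_root <- function(drop, res = 1e-6) {
  x <- seq(res, pi - res, by = res)
  s <- (sin(x) / x)^2
  x[which.min(abs(s - drop))]
}

# small uniform test stack (identical or per-frame constant frames)
make_const_stack <- function(levels, q_db = 10, max_raw = 1000,
                             width = 32L, height = 24L) {
  sp <- scan_params(width_px = width, height_px = height,
                    fov_lateral_mm = 1, fov_axial_mm = 1)
  frames <- lapply(levels, function(l) matrix(l, height, width))
  bscan_stack(frames, timestamps_ms = seq_along(levels) * 50,
              max_raw = rep(max_raw, length(levels)),
              quality_db = rep(q_db, length(levels)),
              params = sp, registered = TRUE)
}

# scan raster large enough that 0.2 degrees moves edge pixels by > half a
# pixel, at the clinical pixel pitch
big_scan <- function() {
  scan_params(width_px = 224L, height_px = 160L,
              fov_lateral_mm = 2.9 * 224 / 1024,
              fov_axial_mm = 1.9 * 160 / 496)
}
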