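#' ECG trace with microsecond timestamps
#'
#' Container for a raw ECG recording as logged by the vitals monitor: integer
#' timestamps in microseconds since epoch and voltage in arbitrary units
#' ("HP value"). `clock_offset_ms` is the constant (in milliseconds) that must
#' be ADDED to the ECG timestamps to place them on the OCT clock; it absorbs
#' the residual offset of the network-time synchronisation between the two
#' devices.
#'
#' Duplicate timestamps are collapsed to the mean of their values before
#' validation, since loggers occasionally emit two samples in the same packet.
#'
#' @param times_us integer-valued timestamps, microseconds since epoch.
#' @param values ECG voltage, arbitrary units.
#' @param clock_offset_ms milliseconds added to ECG times to reach the OCT
#'   clock (default 0).
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(times_us, values, clock_offset_ms = 0) {
  if (length(times_us) != length(values))
    stop("times_us and values must have equal length", call. = FALSE)
  if (anyNA(times_us) || anyNA(values) || !all(is.finite(values)))
    stop("ECG trace contains missing or non-finite entries", call. = FALSE)
  times_us <- as.numeric(times_us)
  if (is.unsorted(times_us))
    stop("ECG timestamps must be non-decreasing", call. = FALSE)
  if (anyDuplicated(times_us)) {
    values <- as.numeric(tapply(values, times_us, mean))
    times_us <- sort(unique(times_us))
  }
  if (length(times_us) < 2L)
    stop("ECG trace needs at least 2 samples", call. = FALSE)
  structure(
    list(times_us = times_us, values = as.numeric(values),
         clock_offset_ms = as.numeric(clock_offset_ms)),
    class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  span_s <- (x$times_us[length(x$times_us)] - x$times_us[1]) / 1e6
  cat(sprintf("<ecg_trace> %d samples over %.2f s, clock offset %+.1f ms\n",
              length(x$values), span_s, x$clock_offset_ms))
  invisible(x)
}

#' Read an ECG CSV file
#'
#' Expects a header row and at least the columns `timestamp_us` (integer
#' microseconds) and `hp_value` (voltage, arbitrary units); extra columns are
#' ignored.
#'
#' @param path CSV file path.
#' @param clock_offset_ms see [ecg_trace()].
#' @return An `ecg_trace`.
#' @export
read_ecg_csv <- function(path, clock_offset_ms = 0) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("timestamp_us", "hp_value")
  if (!all(need %in% names(df)))
    stop("ECG CSV must contain columns 'timestamp_us' and 'hp_value'",
         call. = FALSE)
  ecg_trace(df$timestamp_us, df$hp_value, clock_offset_ms = clock_offset_ms)
}

#' Write an ECG trace to CSV
#' @param trace an `ecg_trace`.
#' @param path output CSV path.
#' @export
write_ecg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ecg_trace"))
  df <- data.frame(timestamp_us = sprintf("%.0f", trace$times_us),
                   hp_value = trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Uniformly sampled signal on the OCT clock
#'
#' @param t0_ms timestamp of the first sample (ms, OCT clock).
#' @param rate_hz sampling rate, Hz.
#' @param values numeric samples.
#' @return An object of class `uniform_signal`. Implied sample times are
#'   `t0_ms + (i-1) * 1000 / rate_hz`.
#' @export
uniform_signal <- function(t0_ms, rate_hz, values) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar", call. = FALSE)
  if (anyNA(values) || !all(is.finite(values)))
    stop("signal values must be finite", call. = FALSE)
  structure(list(t0_ms = as.numeric(t0_ms), rate_hz = as.numeric(rate_hz),
                 values = as.numeric(values)),
            class = "uniform_signal")
}

#' Sample times of a uniform signal
#' @param signal a `uniform_signal`.
#' @return numeric vector of times in ms on the OCT clock.
#' @export
signal_times_ms <- function(signal) {
  signal$t0_ms + (seq_along(signal$values) - 1) * 1000 / signal$rate_hz
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz from t = %.1f ms\n",
              length(x$values), x$rate_hz, x$t0_ms))
  invisible(x)
}

#' Resample an ECG trace onto a fixed-interval grid
#'
#' Places the trace on the OCT clock (adding `clock_offset_ms`), then linearly
#' interpolates onto a uniform grid at `rate_hz` spanning the recording
#' (missing values between samples are filled by the interpolation; the grid
#' never extrapolates beyond the trace).
#'
#' @param trace an `ecg_trace`.
#' @param rate_hz target rate in Hz (the monitor's native rate is 125 Hz).
#' @return A `uniform_signal` on the OCT clock.
#' @export
resample_ecg <- function(trace, rate_hz = 125) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  t_ms <- trace$times_us / 1000 + trace$clock_offset_ms
  step <- 1000 / rate_hz
  n <- floor((t_ms[length(t_ms)] - t_ms[1]) / step) + 1
  grid <- t_ms[1] + (seq_len(n) - 1) * step
  vals <- stats::approx(t_ms, trace$values, xout = grid, method = "linear",
                        rule = 1)$y
  uniform_signal(t0_ms = t_ms[1], rate_hz = rate_hz, values = vals)
}

#' Train of physiological events
#'
#' @param times_ms strictly increasing event times (ms, OCT clock).
#' @param kind `"r_peak"` or `"pulse_arrival"`.
#' @return An object of class `peak_train`.
#' @export
peak_train <- function(times_ms, kind = c("r_peak", "pulse_arrival")) {
  kind <- match.arg(kind)
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) && (anyNA(times_ms) ||
      (length(times_ms) > 1 && any(diff(times_ms) <= 0))))
    stop("event times must be strictly increasing and finite", call. = FALSE)
  structure(list(times_ms = times_ms, kind = kind), class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d %s events\n", length(x$times_ms), x$kind))
  invisible(x)
}

#' Mean RR interval of a peak train
#'
#' The heart rate follows directly from the detected R-peaks; this returns the
#' arithmetic mean of the successive inter-event intervals in milliseconds.
#'
#' @param train a `peak_train` with at least 2 events.
#' @return mean interval in ms.
#' @export
mean_rr_ms <- function(train) {
  stopifnot(inherits(train, "peak_train"))
  if (length(train$times_ms) < 2L)
    stop("need at least 2 events to compute a mean interval", call. = FALSE)
  mean(diff(train$times_ms))
}

# Gaussian kernel truncated at 4 sigma, renormalized to unit sum.
gaussian_kernel <- function(sigma) {
  half <- max(1L, floor(4 * sigma))
  j <- seq.int(-half, half)
  k <- exp(-j^2 / (2 * sigma^2))
  k / sum(k)
}

# "Same"-length convolution with zero padding at the edges.
conv_same <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  out <- as.numeric(stats::filter(padded, k, method = "convolution", sides = 2))
  out[(half + 1L):(half + n)]
}

#' Encode an event train as a smoothed [0,1] signal on a grid
#'
#' Events are binarised along the time axis: each event becomes a unit impulse
#' at the nearest grid sample (ties round toward the earlier sample), the
#' impulse train is convolved with a discrete Gaussian (sigma in samples,
#' kernel truncated at 4 sigma and renormalised to unit sum) and finally
#' divided by its maximum so that the largest value is exactly 1. An empty
#' train encodes to all zeros. Events outside the grid span are dropped with a
#' warning.
#'
#' @param train a `peak_train`.
#' @param t0_ms,rate_hz,n_samples the target grid.
#' @param sigma_samples Gaussian standard deviation in grid samples
#'   (default 1.25).
#' @return An object of class `encoded_train` (also a `uniform_signal` in its
#'   `$signal` field).
#' @export
encode_train <- function(train, t0_ms, rate_hz, n_samples,
                         sigma_samples = 1.25) {
  stopifnot(inherits(train, "peak_train"))
  if (rate_hz <= 0 || n_samples < 1)
    stop("grid must have positive rate and length", call. = FALSE)
  if (sigma_samples <= 0) stop("sigma_samples must be positive", call. = FALSE)
  step <- 1000 / rate_hz
  x <- numeric(n_samples)
  if (length(train$times_ms)) {
    frac <- (train$times_ms - t0_ms) / step
    idx <- ceiling(frac - 0.5) + 1L  # nearest sample, ties toward earlier
    keep <- idx >= 1L & idx <= n_samples
    if (!all(keep))
      warning(sum(!keep), " event(s) outside the encoding grid were dropped")
    for (i in idx[keep]) x[i] <- x[i] + 1
    if (any(keep)) {
      x <- conv_same(x, gaussian_kernel(sigma_samples))
      x <- x / max(x)
    }
  }
  structure(
    list(signal = uniform_signal(t0_ms, rate_hz, x),
         sigma_samples = sigma_samples, source = train),
    class = "encoded_train")
}

#' @export
print.encoded_train <- function(x, ...) {
  cat(sprintf("<encoded_train> %d samples @ %g Hz from %d %s events\n",
              length(x$signal$values), x$signal$rate_hz,
              length(x$source$times_ms), x$source$kind))
  invisible(x)
}

#' Serialize a peak train or encoded train to JSON
#' @param x a `peak_train` or `encoded_train`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
train_to_json <- function(x, path = NULL) {
  doc <- if (inherits(x, "peak_train")) {
    list(kind = x$kind, times_ms = x$times_ms)
  } else if (inherits(x, "encoded_train")) {
    list(kind = x$source$kind, t0_ms = x$signal$t0_ms,
         rate_hz = x$signal$rate_hz, values = x$signal$values)
  } else stop("unsupported object", call. = FALSE)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
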