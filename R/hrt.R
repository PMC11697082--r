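#' HRT estimation configuration
#'
#' @param grid_rate_hz common analysis grid rate for the event-train encoding
#'   and cross-correlation (default 125 Hz, the ECG rate, giving 8 ms lag
#'   resolution).
#' @param sigma_samples Gaussian smoothing of the encoded trains, in grid
#'   samples (default 1.25).
#' @param pad_before_s ECG window extension before the first B-scan
#'   (default 10 s).
#' @param pad_after_s ECG window extension after the last B-scan
#'   (default 1 s).
#' @return An object of class `hrt_config`.
#' @export
hrt_config <- function(grid_rate_hz = 125, sigma_samples = 1.25,
                       pad_before_s = 10, pad_after_s = 1) {
  vals <- c(grid_rate_hz, sigma_samples, pad_before_s, pad_after_s)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all hrt_config fields must be positive", call. = FALSE)
  structure(list(grid_rate_hz = grid_rate_hz, sigma_samples = sigma_samples,
                 pad_before_s = pad_before_s, pad_after_s = pad_after_s),
            class = "hrt_config")
}

#' Normalised cross-correlation of two encoded event trains
#'
#' Computes `cc(lag) = sum_t O(t) * E(t + lag) / sqrt(sum O^2 * sum E^2)` for
#' every integer-sample lag at which the (padded) ECG window fully covers the
#' shifted OCT support. The OCT train is the baseline: a negative argmax lag
#' means the ECG pattern precedes the OCT pattern.
#'
#' @param oct_train,ecg_train `encoded_train` objects on the same grid rate,
#'   with sample grids phase-aligned.
#' @param demean subtract each train's mean before correlating (default
#'   FALSE: the trains are non-negative bump sequences with max 1, so the
#'   energy-normalised form is used as-is).
#' @return list with `lags_ms` and `cc`.
#' @export
cross_correlate_trains <- function(oct_train, ecg_train, demean = FALSE) {
  stopifnot(inherits(oct_train, "encoded_train"),
            inherits(ecg_train, "encoded_train"))
  o <- oct_train$signal; e <- ecg_train$signal
  if (abs(o$rate_hz - e$rate_hz) > 1e-9)
    stop("trains must share the same grid rate", call. = FALSE)
  step <- 1000 / o$rate_hz
  delta <- (o$t0_ms - e$t0_ms) / step
  if (abs(delta - round(delta)) > 1e-6)
    stop("train grids are not phase-aligned", call. = FALSE)
  delta <- as.integer(round(delta))
  ov <- o$values; ev <- e$values
  if (isTRUE(demean)) {
    ov <- ov - mean(ov); ev <- ev - mean(ev)
  }
  so <- sum(ov^2); se <- sum(ev^2)
  if (so == 0 || se == 0)
    stop("cannot cross-correlate an all-zero train", call. = FALSE)
  no <- length(ov); ne <- length(ev)
  shifts <- seq.int(-delta, ne - no - delta)
  if (!length(shifts) || shifts[1] > 0)
    stop("ECG window does not cover the OCT span", call. = FALSE)
  cc <- vapply(shifts, function(s) {
    sum(ov * ev[(delta + s + 1):(delta + s + no)])
  }, numeric(1)) / sqrt(so * se)
  list(lags_ms = shifts * step, cc = cc)
}

# argmax with ties broken toward the smallest |lag|
argmax_lag <- function(lags, cc) {
  best <- max(cc)
  cand <- which(cc >= best - 1e-12)
  lags[cand[which.min(abs(lags[cand]))]]
}

#' Estimate the heart-retina time from two event trains
#'
#' Encodes the pulse-arrival and R-peak trains on a common grid (the OCT span
#' defines the base window; the ECG window is padded per the configuration),
#' cross-correlates them, and takes the cross-correlation argmax restricted
#' to lags within one mean cardiac cycle `[-rr_mean, 0]` as the most probable
#' offset of the ECG to the OCT. The HRT is the additive inverse of that
#' offset. If the unrestricted argmax falls outside one cardiac cycle the
#' estimate is flagged as an outlier.
#'
#' Each train is smoothed with `sigma_samples` in units of its own native
#' sampling: the ECG train's native grid is the common analysis grid (both
#' default to 125 Hz), while the pulse-arrival times are only resolved to the
#' B-scan frame interval, so the arrival train's Gaussian width is scaled by
#' `event_res_ms` relative to the grid step. This matches the smoothing's
#' purpose - allowing for the uncertainty of each detection - and keeps the
#' true-lag coherence from collapsing at coarse frame rates.
#'
#' @param arrivals `peak_train` of pulse arrivals (>= 2 events).
#' @param r_peaks `peak_train` of ECG R-peaks (>= 2 events).
#' @param cfg an `hrt_config`.
#' @param oct_span_ms optional two-vector giving the OCT acquisition span on
#'   the OCT clock; defaults to the span of the arrival train.
#' @param event_res_ms native temporal resolution of the arrival detection
#'   (the B-scan frame interval); `NULL` (default) uses the grid step, i.e.
#'   both trains are smoothed identically.
#' @return An object of class `hrt_estimate` with `lags_ms`, `cc`,
#'   `offset_ms`, `hrt_ms = -offset_ms`, `rr_mean_ms` and `is_outlier`.
#' @export
estimate_hrt <- function(arrivals, r_peaks, cfg = hrt_config(),
                         oct_span_ms = NULL, event_res_ms = NULL) {
  stopifnot(inherits(arrivals, "peak_train"), inherits(r_peaks, "peak_train"))
  if (length(arrivals$times_ms) < 2L || length(r_peaks$times_ms) < 2L)
    stop("need at least 2 events in each train", call. = FALSE)
  if (is.null(oct_span_ms)) oct_span_ms <- range(arrivals$times_ms)
  step <- 1000 / cfg$grid_rate_hz
  n_oct <- ceiling((oct_span_ms[2] - oct_span_ms[1]) / step) + 1L
  pad_b <- ceiling(cfg$pad_before_s * 1000 / step)
  pad_a <- ceiling(cfg$pad_after_s * 1000 / step)
  t0_ecg <- oct_span_ms[1] - pad_b * step
  n_ecg <- pad_b + n_oct + pad_a
  keep <- r_peaks$times_ms >= t0_ecg - step / 2 &
    r_peaks$times_ms <= t0_ecg + n_ecg * step + step / 2
  ecg_window <- peak_train(r_peaks$times_ms[keep], kind = "r_peak")
  sigma_oct <- cfg$sigma_samples
  if (!is.null(event_res_ms) && event_res_ms > step)
    sigma_oct <- cfg$sigma_samples * event_res_ms / step
  oct_enc <- encode_train(arrivals, oct_span_ms[1], cfg$grid_rate_hz, n_oct,
                          sigma_oct)
  ecg_enc <- encode_train(ecg_window, t0_ecg, cfg$grid_rate_hz, n_ecg,
                          cfg$sigma_samples)
  xc <- cross_correlate_trains(oct_enc, ecg_enc)
  rr <- mean_rr_ms(r_peaks)
  in_cycle <- xc$lags_ms >= -rr & xc$lags_ms <= 0
  if (!any(in_cycle))
    stop("no lags within one cardiac cycle; windows do not overlap",
         call. = FALSE)
  offset <- argmax_lag(xc$lags_ms[in_cycle], xc$cc[in_cycle])
  global_offset <- argmax_lag(xc$lags_ms, xc$cc)
  structure(list(lags_ms = xc$lags_ms, cc = xc$cc,
                 offset_ms = offset, hrt_ms = -offset,
                 global_offset_ms = global_offset, rr_mean_ms = rr,
                 is_outlier = (global_offset < -rr || global_offset > 0)),
            class = "hrt_estimate")
}

#' @export
print.hrt_estimate <- function(x, ...) {
  cat(sprintf("<hrt_estimate> HRT %.1f ms (offset %.1f ms, RR %.0f ms)%s\n",
              x$hrt_ms, x$offset_ms, x$rr_mean_ms,
              if (x$is_outlier) " [outlier]" else ""))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean.
#'
#' @param values numeric vector with at least 2 values and non-zero mean.
#' @return the coefficient of variation.
#' @export
cv <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values for a coefficient of variation",
         call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  stats::sd(values) / m
}

#' Cohort record table constructor
#'
#' @param subject_id,exam_id,vessel_id identifier vectors (non-empty strings).
#' @param hrt_ms estimated HRT per record, ms.
#' @param is_outlier logical one-cycle-rule flag per record.
#' @return data.frame of class `cohort_records`.
#' @export
cohort_records <- function(subject_id, exam_id, vessel_id, hrt_ms,
                           is_outlier = FALSE) {
  df <- data.frame(subject_id = as.character(subject_id),
                   exam_id = as.character(exam_id),
                   vessel_id = as.character(vessel_id),
                   hrt_ms = as.numeric(hrt_ms),
                   is_outlier = rep_len(as.logical(is_outlier),
                                        length(hrt_ms)))
  if (any(!nzchar(df$subject_id)) || any(!nzchar(df$exam_id)) ||
      any(!nzchar(df$vessel_id)))
    stop("ids must be non-empty", call. = FALSE)
  class(df) <- c("cohort_records", "data.frame")
  df
}

group_cv <- function(values, groups) {
  per <- vapply(split(values, groups),
                function(v) if (length(v) >= 2L) cv(v) else NA_real_,
                numeric(1))
  per <- per[!is.na(per)]
  if (!length(per)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(per), sd = if (length(per) >= 2L) stats::sd(per) else NA_real_)
}

#' Reproducibility report: coefficients of variation of the HRT
#'
#' Computes the inter-subject CoV (over per-subject mean HRTs), and the
#' mean +/- SD of the per-group CoV for intra-subject (all records of one
#' subject), intra-exam (vessels within one exam) and intra-vessel (same
#' vessel across exams) groupings. Groups with fewer than 2 members do not
#' contribute; a statistic with no eligible group is reported as `NA`.
#' Records flagged as outliers are excluded.
#'
#' @param records a `cohort_records` data.frame.
#' @return An object of class `cov_report`.
#' @export
cov_report <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  r <- records[!records$is_outlier, , drop = FALSE]
  if (!nrow(r)) stop("all records are flagged as outliers", call. = FALSE)
  subj_means <- vapply(split(r$hrt_ms, r$subject_id), mean, numeric(1))
  inter <- if (length(subj_means) >= 2L) cv(subj_means) else NA_real_
  intra_subj <- group_cv(r$hrt_ms, r$subject_id)
  intra_exam <- group_cv(r$hrt_ms, paste(r$subject_id, r$exam_id, sep = "/"))
  intra_vessel <- group_cv(r$hrt_ms,
                           paste(r$subject_id, r$vessel_id, sep = "/"))
  structure(list(
    inter_subject_cov = inter,
    intra_subject_cov_mean = intra_subj[["mean"]],
    intra_subject_cov_sd = intra_subj[["sd"]],
    intra_exam_cov_mean = intra_exam[["mean"]],
    intra_exam_cov_sd = intra_exam[["sd"]],
    intra_vessel_cov_mean = intra_vessel[["mean"]],
    intra_vessel_cov_sd = intra_vessel[["sd"]],
    overall_mean_ms = mean(r$hrt_ms),
    overall_sd_ms = if (nrow(r) >= 2L) stats::sd(r$hrt_ms) else NA_real_,
    overall_mean_ms_incl_outliers = mean(records$hrt_ms),
    overall_sd_ms_incl_outliers =
      if (nrow(records) >= 2L) stats::sd(records$hrt_ms) else NA_real_,
    n_records = nrow(r), n_outliers_excluded = sum(records$is_outlier)),
    class = "cov_report")
}

#' @export
print.cov_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat(sprintf(
    paste0("<cov_report> HRT %.1f +/- %.1f ms over %d records",
           " (%d outliers excluded)\n",
           "  inter-subject CoV %s\n",
           "  intra-subject CoV %s +/- %s\n",
           "  intra-exam    CoV %s +/- %s\n",
           "  intra-vessel  CoV %s +/- %s\n"),
    x$overall_mean_ms, x$overall_sd_ms, x$n_records, x$n_outliers_excluded,
    fmt(x$inter_subject_cov),
    fmt(x$intra_subject_cov_mean), fmt(x$intra_subject_cov_sd),
    fmt(x$intra_exam_cov_mean), fmt(x$intra_exam_cov_sd),
    fmt(x$intra_vessel_cov_mean), fmt(x$intra_vessel_cov_sd)))
  invisible(x)
}
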