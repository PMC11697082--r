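#' Per-vessel signal panels
#'
#' Five stacked panels over a shared time axis: subarea SNR, the
#' multi-branch velocity scatter coloured by numerical solution index (NSI),
#' the envelope gradient with detected pulse arrivals, the resampled ECG with
#' R-peaks, and the two encoded event trains overlaid.
#'
#' @param res an `exam_result`.
#' @param vessel_id which vessel to plot.
#' @param path optional PNG path; `NULL` draws on the current device.
#' @export
plot_exam_panels <- function(res, vessel_id, path = NULL) {
  v <- res$vessels[[vessel_id]]
  if (is.null(v) || !is.null(v$error))
    stop("no analysable vessel ", vessel_id, call. = FALSE)
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 1400, res = 130)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(5, 1), mar = c(2.5, 4, 1.5, 1),
                      mgp = c(2.2, 0.7, 0))
  # restore par before any png device is closed
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  t_s <- v$series$timestamps_ms / 1000

  graphics::plot(t_s, v$series$snr, type = "l", col = "steelblue",
                 xlab = "", ylab = "subarea SNR",
                 main = paste("vessel", vessel_id))
  nsi <- v$solutions$nsi
  cols <- grDevices::hcl.colors(max(nsi) + 1L, "viridis")
  graphics::plot(v$solutions$timestamp_ms / 1000, v$solutions$v,
                 col = cols[nsi + 1L], pch = 16, cex = 0.5,
                 xlab = "", ylab = "axial velocity [mm/s]")
  graphics::lines(t_s, v$profile$envelope_v, col = "grey40", lwd = 0.8)
  graphics::plot(t_s, v$profile$gradient, type = "l", col = "darkorange",
                 xlab = "", ylab = "velocity gradient")
  graphics::abline(v = v$arrivals$times_ms / 1000, col = "red", lty = 3)
  ecg_t <- signal_times_ms(res$ecg_signal) / 1000
  keep <- ecg_t >= min(t_s) - 1 & ecg_t <= max(t_s) + 1
  graphics::plot(ecg_t[keep], res$ecg_signal$values[keep], type = "l",
                 xlab = "", ylab = "ECG [HP value]")
  graphics::abline(v = res$r_peaks$times_ms / 1000, col = "red", lty = 3)
  graphics::plot(NULL, xlim = range(t_s), ylim = c(0, 1),
                 xlab = "time since OCT start [s]", ylab = "encoded trains")
  graphics::segments(res$r_peaks$times_ms / 1000, 0,
                     res$r_peaks$times_ms / 1000, 1, col = "red")
  graphics::segments(v$arrivals$times_ms / 1000, 0,
                     v$arrivals$times_ms / 1000, 1, col = "blue", lty = 2)
  graphics::legend("topright", legend = c("R-peaks", "pulse arrivals"),
                   col = c("red", "blue"), lty = c(1, 2), bty = "n",
                   cex = 0.8)
  invisible(NULL)
}

#' Cross-correlation curve of an HRT estimate
#'
#' @param est an `hrt_estimate`.
#' @param path optional PNG path.
#' @export
plot_cross_correlation <- function(est, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 1000, height = 500, res = 130)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(est$lags_ms, est$cc, type = "l",
                 xlab = "ECG-to-OCT lag [ms]",
                 ylab = "normalised cross-correlation",
                 main = sprintf("offset %.0f ms, HRT %.0f ms%s",
                                est$offset_ms, est$hrt_ms,
                                if (est$is_outlier) " (outlier)" else ""))
  graphics::abline(v = est$offset_ms, col = "red", lty = 2)
  graphics::abline(v = c(-est$rr_mean_ms, 0), col = "grey60", lty = 3)
  invisible(NULL)
}

#' Histogram of unrestricted cross-correlation argmax offsets
#'
#' @param offsets_ms numeric vector of offsets.
#' @param bin_ms histogram bin width (default 50 ms).
#' @param path optional PNG path.
#' @export
plot_offset_histogram <- function(offsets_ms, bin_ms = 50, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 500, res = 130)
    on.exit(grDevices::dev.off())
  }
  lo <- floor(min(offsets_ms) / bin_ms) * bin_ms
  hi <- ceiling(max(offsets_ms) / bin_ms) * bin_ms
  if (hi <= lo) hi <- lo + bin_ms
  graphics::hist(offsets_ms, breaks = seq(lo, hi, by = bin_ms),
                 col = "steelblue", border = "white",
                 xlab = "cross-correlation argmax offset [ms]",
                 main = "most probable ECG-to-OCT offsets")
  invisible(NULL)
}
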