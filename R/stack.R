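#' OCT scan geometry and physics parameters
#'
#' Defaults follow the clinical acquisition: 880 nm central wavelength, bulk
#' refractive index 1.36 (average for the eye), B-scans of 1024 x 496
#' (lateral x axial) pixels over a field of view of roughly 2.9 mm x 1.9 mm,
#' and a per-A-scan integration time of 44.8 us (20 kHz nominal line rate) or
#' 11.2 us (85 kHz).
#'
#' @param wavelength_m central wavelength of the light source, metres.
#' @param refractive_index bulk refractive index along the beam.
#' @param integration_time_s per-A-scan integration (exposure) time, seconds.
#' @param width_px,height_px B-scan size in pixels (lateral, axial).
#' @param fov_lateral_mm,fov_axial_mm physical field of view, millimetres.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(wavelength_m = 880e-9, refractive_index = 1.36,
                        integration_time_s = 44.8e-6,
                        width_px = 1024L, height_px = 496L,
                        fov_lateral_mm = 2.9, fov_axial_mm = 1.9) {
  p <- list(wavelength_m = wavelength_m, refractive_index = refractive_index,
            integration_time_s = integration_time_s,
            width_px = as.integer(width_px), height_px = as.integer(height_px),
            fov_lateral_mm = fov_lateral_mm, fov_axial_mm = fov_axial_mm)
  if (any(vapply(p, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("all scan parameters must be positive and finite", call. = FALSE)
  if (wavelength_m <= 400e-9 || wavelength_m >= 1600e-9)
    stop("wavelength outside the plausible OCT range", call. = FALSE)
  if (refractive_index < 1)
    stop("refractive index must be >= 1", call. = FALSE)
  structure(p, class = "scan_params")
}

#' Physical size of a vessel subarea window
#'
#' Converts the (2h+1) x (2h+1) pixel analysis window to micrometres using the
#' scan raster. At the default geometry a 7 x 7 window spans roughly
#' 20 um laterally by 27 um axially.
#'
#' @param params a `scan_params`.
#' @param half_width window half width in pixels (default 3, i.e. 7 x 7).
#' @return named numeric `c(lateral_um, axial_um)`.
#' @export
subarea_size_um <- function(params, half_width = 3L) {
  side <- 2L * as.integer(half_width) + 1L
  c(lateral_um = side * params$fov_lateral_mm / params$width_px * 1000,
    axial_um = side * params$fov_axial_mm / params$height_px * 1000)
}

#' Time-resolved B-scan stack
#'
#' Frames are height x width matrices of normalised intensity in \[0,1\]
#' (rows = axial, columns = lateral). Per-frame metadata carries the
#' acquisition timestamp (ms, OCT clock), the maximum raw intensity of the
#' frame, and the device quality score Q (B-scan SNR in dB, power ratio).
#'
#' @param frames list of numeric matrices with values in \[0,1\].
#' @param timestamps_ms per-frame timestamps, strictly increasing.
#' @param max_raw per-frame maximum raw intensity.
#' @param quality_db per-frame quality score, dB, > 0.
#' @param params a `scan_params`.
#' @param registered logical; whether the stack has been registered.
#' @return An object of class `bscan_stack`.
#' @export
bscan_stack <- function(frames, timestamps_ms, max_raw, quality_db, params,
                        registered = FALSE) {
  n <- length(frames)
  if (n < 2L) stop("a stack needs at least 2 frames", call. = FALSE)
  if (length(timestamps_ms) != n || length(max_raw) != n ||
      length(quality_db) != n)
    stop("per-frame metadata must match the number of frames", call. = FALSE)
  if (any(diff(timestamps_ms) <= 0))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  if (any(quality_db <= 0))
    stop("quality_db must be positive", call. = FALSE)
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims))
      stop("all frames must be matrices of identical size", call. = FALSE)
    rng <- range(f)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
      stop("frame intensities must lie in [0, 1]", call. = FALSE)
  }
  if (dims[1] != params$height_px || dims[2] != params$width_px)
    stop("frame size does not match scan_params", call. = FALSE)
  structure(list(frames = frames, timestamps_ms = as.numeric(timestamps_ms),
                 max_raw = as.numeric(max_raw),
                 quality_db = as.numeric(quality_db),
                 params = params, registered = isTRUE(registered)),
            class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<bscan_stack> %d frames of %d x %d px, %s, %.2f s span\n",
              length(x$frames), d[1], d[2],
              if (x$registered) "registered" else "unregistered",
              diff(range(x$timestamps_ms)) / 1000))
  invisible(x)
}

#' Per-frame vessel-centre annotations
#'
#' Pixel coordinates are 0-based with `x` the lateral column and `y` the axial
#' row; every centre must keep the full analysis window inside the image.
#'
#' @param centers_px two-column matrix (x, y), one row per frame.
#' @param vessel_id identifier string.
#' @param subarea_half_width analysis half window (default 3, i.e. 7 x 7).
#' @param stack optional `bscan_stack` to validate length and margins against.
#' @return An object of class `vessel_track`.
#' @export
vessel_track <- function(centers_px, vessel_id = "A1", subarea_half_width = 3L,
                         stack = NULL) {
  centers_px <- as.matrix(centers_px)
  if (ncol(centers_px) != 2L) stop("centers_px must have two columns (x, y)",
                                   call. = FALSE)
  storage.mode(centers_px) <- "integer"
  h <- as.integer(subarea_half_width)
  if (h < 1L) stop("subarea_half_width must be >= 1", call. = FALSE)
  if (!nzchar(vessel_id)) stop("vessel_id must be non-empty", call. = FALSE)
  tr <- structure(list(centers_px = centers_px, vessel_id = vessel_id,
                       subarea_half_width = h), class = "vessel_track")
  if (!is.null(stack)) validate_track(tr, stack)
  tr
}

validate_track <- function(track, stack) {
  if (nrow(track$centers_px) != length(stack$frames))
    stop("annotation length does not match the stack", call. = FALSE)
  h <- track$subarea_half_width
  w <- stack$params$width_px; hh <- stack$params$height_px
  x <- track$centers_px[, 1]; y <- track$centers_px[, 2]
  if (any(x < h | x > w - 1L - h | y < h | y > hh - 1L - h))
    stop("vessel centre closer than the window half width to the image border",
         call. = FALSE)
  invisible(TRUE)
}

#' Intensity transform for display
#'
#' Maps normalised intensities to display values `255 * I^(1/4)`; strictly
#' monotone, so pixel rank order is preserved.
#'
#' @param frame numeric array with values in \[0,1\].
#' @return array of the same shape with values in \[0,255\].
#' @export
visualization_transform <- function(frame) {
  rng <- range(frame)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  255 * frame^0.25
}

#' Registration reference image
#'
#' Pixelwise mean of the first `n_frames` frames of the stack; serves as the
#' fixed image for rigid registration.
#'
#' @param stack a `bscan_stack`.
#' @param n_frames number of leading frames to average (default 10).
#' @return a matrix of mean intensities.
#' @export
build_reference <- function(stack, n_frames = 10L) {
  stopifnot(inherits(stack, "bscan_stack"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L || n_frames > length(stack$frames))
    stop("n_frames must be between 1 and the stack length", call. = FALSE)
  Reduce(`+`, stack$frames[seq_len(n_frames)]) / n_frames
}

#' Vessel-subarea SNR time series
#'
#' For each frame the mean normalised intensity over the (2h+1) x (2h+1)
#' window centred on the annotated vessel centre is converted to a linear SNR:
#' the B-scan noise level is approximated (shot-noise limited detection) as
#' the frame's maximum raw intensity divided by the quality score converted
#' from dB to a linear power ratio, and the mean raw window intensity is
#' divided by that noise level. The series is then normalised by the reference
#' SNR - the peak single-pixel SNR over the whole series within the window -
#' to give the per-frame SNR drop in (0, 1] (values above 1, possible with
#' noise, are clipped).
#'
#' @param stack a registered `bscan_stack`.
#' @param track a `vessel_track` valid for the stack.
#' @return An object of class `subarea_series` with fields `mean_intensity`,
#'   `snr`, `reference_snr`, `snr_drop`, `timestamps_ms`.
#' @export
extract_subarea_series <- function(stack, track) {
  stopifnot(inherits(stack, "bscan_stack"), inherits(track, "vessel_track"))
  if (!stack$registered)
    stop("stack must be registered before subarea extraction", call. = FALSE)
  validate_track(track, stack)
  h <- track$subarea_half_width
  n <- length(stack$frames)
  mean_int <- numeric(n); snr <- numeric(n); peak_px <- numeric(n)
  for (i in seq_len(n)) {
    cx <- track$centers_px[i, 1] + 1L  # to 1-based
    cy <- track$centers_px[i, 2] + 1L
    win <- stack$frames[[i]][(cy - h):(cy + h), (cx - h):(cx + h)]
    noise <- stack$max_raw[i] / 10^(stack$quality_db[i] / 10)
    mean_int[i] <- mean(win)
    snr[i] <- mean_int[i] * stack$max_raw[i] / noise
    peak_px[i] <- max(win) * stack$max_raw[i] / noise
  }
  reference_snr <- max(peak_px)
  structure(list(mean_intensity = mean_int, snr = snr,
                 reference_snr = reference_snr,
                 snr_drop = pmin(snr / reference_snr, 1),
                 timestamps_ms = stack$timestamps_ms,
                 vessel_id = track$vessel_id),
            class = "subarea_series")
}

#' @export
print.subarea_series <- function(x, ...) {
  cat(sprintf(
    "<subarea_series> vessel %s, %d frames, snr_drop in [%.3g, %.3g]\n",
    x$vessel_id, length(x$snr), min(x$snr_drop), max(x$snr_drop)))
  invisible(x)
}

#' Write a B-scan stack container
#'
#' The container is a directory holding `meta.json` (scan parameters and
#' per-frame metadata) and `frames.bin`, a contiguous little-endian float32
#' array of shape frames x height x width in row-major order, values in
#' \[0,1\].
#'
#' @param stack a `bscan_stack`.
#' @param dir output directory (created if missing).
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "bscan_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- stack$params
  meta <- list(
    scan_params = p[c("wavelength_m", "refractive_index", "integration_time_s",
                      "width_px", "height_px", "fov_lateral_mm",
                      "fov_axial_mm")],
    n_frames = length(stack$frames),
    timestamps_ms = stack$timestamps_ms, max_raw = stack$max_raw,
    quality_db = stack$quality_db, registered = stack$registered)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "frames.bin"), "wb")
  on.exit(close(con))
  for (f in stack$frames)  # row-major: transpose column-major R matrices
    writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
  invisible(dir)
}

#' Read a B-scan stack container
#' @param dir directory written by [write_stack()].
#' @return a `bscan_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sp <- do.call(scan_params, meta$scan_params)
  n <- meta$n_frames
  npx <- sp$height_px * sp$width_px
  bin <- file.path(dir, "frames.bin")
  if (file.info(bin)$size != 4 * n * npx)
    stop("frames.bin size does not match metadata", call. = FALSE)
  con <- file(bin, "rb")
  on.exit(close(con))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    v <- readBin(con, "numeric", n = npx, size = 4L, endian = "little")
    # stored row-major; fill a width x height matrix and transpose back
    frames[[i]] <- t(matrix(v, nrow = sp$width_px, ncol = sp$height_px))
  }
  # float32 round-off can leave values epsilon outside [0,1]
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  bscan_stack(frames, meta$timestamps_ms, meta$max_raw, meta$quality_db,
              sp, registered = isTRUE(meta$registered))
}

#' Read vessel-centre annotations
#'
#' CSV with columns `frame_index, x_px, y_px, vessel_id` (0-based indices),
#' one row per frame per vessel.
#'
#' @param path CSV path.
#' @param subarea_half_width analysis half window for the resulting tracks.
#' @return named list of `vessel_track` objects, one per vessel id.
#' @export
read_annotations <- function(path, subarea_half_width = 3L) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "x_px", "y_px", "vessel_id")
  if (!all(need %in% names(df)))
    stop("annotation CSV must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$vessel_id), function(d) {
    d <- d[order(d$frame_index), ]
    vessel_track(cbind(d$x_px, d$y_px), vessel_id = as.character(d$vessel_id[1]),
                 subarea_half_width = subarea_half_width)
  })
  out
}

#' Write vessel-centre annotations
#' @param tracks list of `vessel_track` objects.
#' @param path output CSV path.
#' @export
write_annotations <- function(tracks, path) {
  if (inherits(tracks, "vessel_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(frame_index = seq_len(nrow(tr$centers_px)) - 1L,
               x_px = tr$centers_px[, 1], y_px = tr$centers_px[, 2],
               vessel_id = tr$vessel_id)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
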