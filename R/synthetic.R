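#' Configuration of the synthetic ECG + OCT forward model
#'
#' Defaults emulate the clinical acquisition regimes: ~7 s continuous
#' B-scanning, ECG sampled at 125 Hz, frame rates near 20 Hz (44.8 us
#' integration) or 74 Hz (11.2 us), and a heart-retina delay in the
#' 100-200 ms range. The scan raster defaults to a 96 x 72 px crop around the
#' vessel at the clinical pixel pitch (2.9/1024 mm lateral, 1.9/496 mm axial)
#' so that full pipelines run at desk scale.
#'
#' @param seed RNG seed; identical configurations produce identical exams.
#' @param duration_s OCT acquisition duration (default 7 s).
#' @param heart_rate_bpm mean heart rate (default 70).
#' @param rr_jitter_frac uniform per-beat RR jitter fraction (default 0.03).
#' @param true_hrt_ms ground-truth heart-retina delay (default 144 ms).
#' @param frame_rate_hz B-scan frame rate (default 20.4).
#' @param ecg_rate_hz ECG nominal sampling rate (default 125).
#' @param ecg_noise_snr_db additive Gaussian ECG noise level; `Inf` disables
#'   noise (default 20 dB).
#' @param oct_noise_sd additive Gaussian noise on normalised OCT intensities
#'   (default 1e-4, matching a ~40 dB quality score).
#' @param scan a `scan_params` for the simulated raster; `NULL` uses the
#'   96 x 72 crop described above with `integration_time_s`.
#' @param integration_time_s per-A-scan integration time used when `scan` is
#'   `NULL` (default 44.8e-6).
#' @param peak_velocity_mms systolic peak axial velocity in mm/s; `NULL`
#'   picks the velocity whose washout argument is 1.4 rad, keeping the whole
#'   waveform inside the principal sinc^2 lobe (unique inversion).
#' @param clock_offset_ms simulated ECG-to-OCT clock offset: the generated
#'   ECG timestamps are early by this amount and carry it as the trace's
#'   `clock_offset_ms` (default 0).
#' @param jitter_px,jitter_deg per-frame rigid drift amplitude (translation
#'   in pixels, rotation in degrees). Defaults 6 px and 0 deg: observed eye
#'   motion in these acquisitions is predominantly translational.
#' @param n_vessels number of vessels rendered side by side (default 1);
#'   all share the exam's arrival times.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration_s = 7, heart_rate_bpm = 70,
                       rr_jitter_frac = 0.03, true_hrt_ms = 144,
                       frame_rate_hz = 20.4, ecg_rate_hz = 125,
                       ecg_noise_snr_db = 20, oct_noise_sd = 1e-4,
                       scan = NULL, integration_time_s = 44.8e-6,
                       peak_velocity_mms = NULL, clock_offset_ms = 0,
                       jitter_px = 6, jitter_deg = 0, n_vessels = 1L) {
  if (is.null(scan))
    scan <- scan_params(integration_time_s = integration_time_s,
                        width_px = 96L, height_px = 72L,
                        fov_lateral_mm = 2.9 * 96 / 1024,
                        fov_axial_mm = 1.9 * 96 / 496)
  wp <- washout_params_from_scan(scan)
  if (is.null(peak_velocity_mms))
    peak_velocity_mms <- x_to_velocity(1.4, wp)
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              heart_rate_bpm = heart_rate_bpm,
              rr_jitter_frac = rr_jitter_frac, true_hrt_ms = true_hrt_ms,
              frame_rate_hz = frame_rate_hz, ecg_rate_hz = ecg_rate_hz,
              ecg_noise_snr_db = ecg_noise_snr_db,
              oct_noise_sd = oct_noise_sd, scan = scan,
              peak_velocity_mms = peak_velocity_mms,
              clock_offset_ms = clock_offset_ms,
              jitter_px = jitter_px, jitter_deg = jitter_deg,
              n_vessels = as.integer(n_vessels))
  pos <- c(duration_s, heart_rate_bpm, frame_rate_hz, ecg_rate_hz)
  if (any(!is.finite(pos) | pos <= 0))
    stop("rates and durations must be positive", call. = FALSE)
  if (true_hrt_ms < 0 || rr_jitter_frac < 0 || oct_noise_sd < 0 ||
      jitter_px < 0 || jitter_deg < 0 || cfg$n_vessels < 1L)
    stop("invalid sim_config", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# P-QRS-T template: sum of Gaussians around the R time (amplitudes in a.u.)
ecg_template <- function(dt_ms) {
  0.12 * exp(-((dt_ms + 180) / 25)^2 / 2) -
    0.10 * exp(-((dt_ms + 22) / 8)^2 / 2) +
    1.00 * exp(-(dt_ms / 11)^2 / 2) -
    0.18 * exp(-((dt_ms - 22) / 9)^2 / 2) +
    0.28 * exp(-((dt_ms - 280) / 65)^2 / 2)
}

# beat times on the OCT clock covering [start_ms, end_ms]
draw_beats <- function(cfg, start_ms, end_ms) {
  rr <- 60000 / cfg$heart_rate_bpm
  times <- start_ms
  repeat {
    nxt <- times[length(times)] +
      rr * (1 + stats::runif(1, -cfg$rr_jitter_frac, cfg$rr_jitter_frac))
    times <- c(times, nxt)
    if (nxt > end_ms) break
  }
  times
}

#' Generate a synthetic ECG trace
#'
#' Synthesizes beats at jittered RR intervals with a parametric P-QRS-T
#' template (dominant R spike), sampled at the nominal ECG rate with up to
#' 1 ms of per-sample timestamp jitter (exercising the resampling step) and
#' additive Gaussian noise at the configured SNR. The recording spans from
#' 12 s before the first B-scan until 2 s after the last so that the padded
#' HRT window is always covered.
#'
#' @param cfg a `sim_config`.
#' @return list with `trace` (an `ecg_trace`) and `r_peak_times_ms`
#'   (ground-truth R-peak times on the OCT clock).
#' @export
generate_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  generate_ecg_impl(cfg)
}

generate_ecg_impl <- function(cfg) {
  t_lo <- -12000
  t_hi <- cfg$duration_s * 1000 + 2000
  beats <- draw_beats(cfg, t_lo + 500, t_hi)
  beats <- beats[beats <= t_hi - 400]  # keep every QRS fully inside the span
  step <- 1000 / cfg$ecg_rate_hz
  t_ms <- seq(t_lo, t_hi, by = step) +
    stats::runif(length(seq(t_lo, t_hi, by = step)), -1, 1)
  vals <- numeric(length(t_ms))
  for (b in beats) {
    idx <- which(t_ms > b - 450 & t_ms < b + 600)
    if (length(idx)) vals[idx] <- vals[idx] + ecg_template(t_ms[idx] - b)
  }
  if (is.finite(cfg$ecg_noise_snr_db)) {
    noise_sd <- sqrt(mean(vals^2)) / 10^(cfg$ecg_noise_snr_db / 20)
    vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  }
  # arbitrary HP units: scaled and offset like the monitor's ADC output
  hp <- 2048 + 1000 * vals
  times_us <- round((t_ms - cfg$clock_offset_ms) * 1000)
  list(trace = ecg_trace(times_us, hp, clock_offset_ms = cfg$clock_offset_ms),
       r_peak_times_ms = beats)
}

#' Evaluate the ground-truth pulse waveform at given times
#'
#' Each beat launches a pulse at `r_time + true_hrt_ms`: a saturating
#' exponential rise (maximal slope exactly at onset, 10-90% rise within two
#' frame intervals) to the systolic peak, followed by an exponential decay
#' toward a diastolic baseline of 25% of peak.
#'
#' @param cfg a `sim_config`.
#' @param r_times_ms R-peak times (OCT clock).
#' @param at_ms times at which to sample the waveform (typically the frame
#'   timestamps).
#' @return axial velocity in mm/s at `at_ms`.
#' @export
generate_flow_waveform <- function(cfg, r_times_ms, at_ms) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(r_times_ms)) stop("r_times_ms must be non-empty", call. = FALSE)
  peak <- cfg$peak_velocity_mms
  base <- 0.25 * peak
  fi <- 1000 / cfg$frame_rate_hz
  tau_r <- 0.8 * fi          # 10-90% rise = 2.2 * tau_r <= 2 frame intervals
  t_peak <- 2.3 * tau_r
  tau_d <- 280
  arrivals <- sort(r_times_ms) + cfg$true_hrt_ms
  k <- findInterval(at_ms, arrivals)
  v <- rep(base, length(at_ms))
  active <- k >= 1L
  dt <- at_ms[active] - arrivals[k[active]]
  rise <- dt < t_peak
  amp <- peak - base
  vr <- numeric(sum(active))
  vr[rise] <- amp * (1 - exp(-dt[rise] / tau_r)) / (1 - exp(-t_peak / tau_r))
  vr[!rise] <- amp * exp(-(dt[!rise] - t_peak) / tau_d)
  v[active] <- base + vr
  v
}

render_scene <- function(cfg, centers, lumen_levels, texture) {
  h <- cfg$scan$height_px; w <- cfg$scan$width_px
  X <- matrix(rep(seq_len(w), each = h), nrow = h)
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)
  img <- 0.15 + 0.08 * sin(2 * pi * Y / 18)^2 + texture
  band <- Y >= h - 12 & Y <= h - 9       # hyperreflective outer layer
  img[band] <- img[band] + 0.45
  r_v <- 6
  for (j in seq_len(nrow(centers))) {
    cx <- centers[j, 1] + 1; cy <- centers[j, 2] + 1
    r2 <- (X - cx)^2 + (Y - cy)^2
    shadow <- abs(X - cx) <= r_v & Y > cy + r_v + 2
    img[shadow] <- img[shadow] * 0.35
    wall <- r2 > r_v^2 & r2 <= (r_v + 2)^2
    img[wall] <- 0.85
    img[r2 <= r_v^2] <- lumen_levels[j]
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic B-scan stack with ground truth
#'
#' Renders frames with a layered background texture, one or more circular
#' vessels with hyperreflective walls and a hypointense shadow column, and a
#' lumen whose intensity is a constant baseline multiplied by
#' `forward_washout(v(t))` for the ground-truth velocity waveform. Per-frame
#' rigid drift (recorded as ground truth, drawn zero-mean over the first ten
#' frames so that the registration gauge is anchored at the scene pose) and
#' Gaussian sensor noise are then applied. The per-frame quality score is set
#' consistently with the injected noise so that the subarea SNR computation
#' recovers the designed drop sequence.
#'
#' @param cfg a `sim_config`.
#' @return list with `stack` (a `bscan_stack`), `tracks` (list of
#'   `vessel_track`), and `truth` (R-peak times, arrival times, velocity and
#'   washout series, reference-normalised `snr_drop_true`, per-frame true
#'   transforms, vessel centres, `true_hrt_ms`).
#' @export
generate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ecg <- generate_ecg_impl(cfg)   # same stream: ECG and stack stay coupled
  generate_stack_impl(cfg, ecg)
}

generate_stack_impl <- function(cfg, ecg) {
  h <- cfg$scan$height_px; w <- cfg$scan$width_px
  half <- 3L
  n_frames <- floor(cfg$duration_s * cfg$frame_rate_hz) + 1L
  t_frames <- round((seq_len(n_frames) - 1L) * 1000 / cfg$frame_rate_hz)
  v <- generate_flow_waveform(cfg, ecg$r_peak_times_ms, t_frames)
  wp <- washout_params_from_scan(cfg$scan)
  washout <- forward_washout(v, wp)

  # vessel centres, evenly spaced laterally (0-based pixel coordinates)
  cx <- round(w * (seq_len(cfg$n_vessels)) / (cfg$n_vessels + 1)) - 1L
  cy <- rep(round(h * 0.45) - 1L, cfg$n_vessels)
  margin <- half + 9L
  if (any(cx < margin | cx > w - 1L - margin) ||
      any(cy < margin | cy > h - 1L - margin))
    stop("vessel placement violates the subarea margin", call. = FALSE)
  centers <- cbind(cx, cy)

  # smooth static speckle-like texture (helps registration, fixed per exam)
  tex <- matrix(stats::rnorm(h * w, 0, 1), h, w)
  tex <- stats::filter(t(stats::filter(t(tex), rep(1, 3) / 3, sides = 2,
                                       circular = TRUE)),
                       rep(1, 3) / 3, sides = 2, circular = TRUE)
  tex <- matrix(as.numeric(tex), h, w)
  tex <- 0.25 * (tex - min(tex)) / (max(tex) - min(tex))

  L0 <- 0.35
  jx <- stats::runif(n_frames, -0.8, 0.8) * cfg$jitter_px
  jy <- stats::runif(n_frames, -0.8, 0.8) * cfg$jitter_px
  jt <- stats::runif(n_frames, -0.8, 0.8) * cfg$jitter_deg
  n_ref <- min(10L, n_frames)
  jx <- pmin(pmax(jx - mean(jx[seq_len(n_ref)]), -cfg$jitter_px), cfg$jitter_px)
  jy <- pmin(pmax(jy - mean(jy[seq_len(n_ref)]), -cfg$jitter_px), cfg$jitter_px)
  jt <- pmin(pmax(jt - mean(jt[seq_len(n_ref)]), -cfg$jitter_deg),
             cfg$jitter_deg)

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    scene <- render_scene(cfg, centers, rep(L0 * washout[i], cfg$n_vessels),
                          tex)
    f <- if (cfg$jitter_px > 0 || cfg$jitter_deg > 0)
      rigid_warp(scene, jx[i], jy[i], jt[i]) else scene
    if (cfg$oct_noise_sd > 0)
      f <- f + stats::rnorm(h * w, 0, cfg$oct_noise_sd)
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }
  max_raw <- rep(1.04e9, n_frames)
  q_db <- rep(if (cfg$oct_noise_sd > 0) -10 * log10(cfg$oct_noise_sd) else 42,
              n_frames)
  stack <- bscan_stack(frames, t_frames, max_raw, q_db, cfg$scan,
                       registered = FALSE)
  tracks <- lapply(seq_len(cfg$n_vessels), function(j)
    vessel_track(matrix(rep(centers[j, ], each = n_frames), ncol = 2),
                 vessel_id = paste0("A", j), subarea_half_width = half))
  arrivals <- ecg$r_peak_times_ms + cfg$true_hrt_ms
  arrivals <- arrivals[arrivals >= t_frames[1] & arrivals <= max(t_frames)]
  truth <- list(
    r_peak_times_ms = ecg$r_peak_times_ms,
    arrival_times_ms = arrivals,
    true_hrt_ms = cfg$true_hrt_ms,
    velocity_mms = v,
    washout_true = washout,
    snr_drop_true = pmin(washout / max(washout), 1),
    transforms = data.frame(dx = jx, dy = jy, theta_deg = jt),
    centers_px = centers,
    timestamps_ms = t_frames)
  list(stack = stack, tracks = tracks, truth = truth)
}

#' Generate a complete synthetic exam (ECG + stack + annotations + truth)
#'
#' @param cfg a `sim_config`.
#' @return list with `ecg` (an `ecg_trace`), `stack`, `tracks`, `truth`.
#' @export
generate_exam <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ecg <- generate_ecg_impl(cfg)
  out <- generate_stack_impl(cfg, ecg)
  out$ecg <- ecg$trace
  out
}

#' Write an exam bundle to disk
#'
#' Produces `ecg.csv`, a `stack/` container, `annotations.csv`, `truth.json`
#' and `bundle.json` (identifiers) under `dir`.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory.
#' @param subject_id,exam_id identifiers stored in `bundle.json`.
#' @return `dir`, invisibly.
#' @export
write_exam_bundle <- function(cfg, dir, subject_id = "S1", exam_id = "E1") {
  exam <- generate_exam(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ecg_csv(exam$ecg, file.path(dir, "ecg.csv"))
  write_stack(exam$stack, file.path(dir, "stack"))
  write_annotations(exam$tracks, file.path(dir, "annotations.csv"))
  tr <- exam$truth
  tr$centers_px <- NULL
  jsonlite::write_json(
    c(tr, list(clock_offset_ms = cfg$clock_offset_ms)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  jsonlite::write_json(list(subject_id = subject_id, exam_id = exam_id),
                       file.path(dir, "bundle.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Generate a synthetic cohort of exams
#'
#' Draws per-subject mean HRTs from `Normal(base, between_sd_frac * base)`
#' and per-exam HRTs from `Normal(subject mean, within_sd_frac * base)`;
#' all vessels within an exam share the exam's HRT (the pulse waves arrive
#' synchronously).
#'
#' @param n_subjects,exams_per_subject,vessels_per_exam cohort design counts.
#' @param base_cfg a `sim_config`; its `true_hrt_ms` is the cohort base HRT
#'   and its `seed` seeds the cohort draw.
#' @param between_sd_frac,within_sd_frac dispersion fractions (default 0.09
#'   and 0.11).
#' @return list with `bundles` (each: `subject_id`, `exam_id`, `cfg`) and
#'   `truth`, a data.frame of per-exam true HRTs.
#' @export
generate_cohort <- function(n_subjects = 5L, exams_per_subject = 4L,
                            vessels_per_exam = 1L, base_cfg = sim_config(),
                            between_sd_frac = 0.09, within_sd_frac = 0.11) {
  if (n_subjects < 1L || exams_per_subject < 1L || vessels_per_exam < 1L)
    stop("all cohort counts must be >= 1", call. = FALSE)
  if (between_sd_frac < 0 || within_sd_frac < 0)
    stop("dispersion fractions must be non-negative", call. = FALSE)
  set.seed(base_cfg$seed)
  base <- base_cfg$true_hrt_ms
  subj_means <- stats::rnorm(n_subjects, base, between_sd_frac * base)
  bundles <- list(); rows <- list()
  for (s in seq_len(n_subjects)) {
    for (e in seq_len(exams_per_subject)) {
      hrt <- stats::rnorm(1, subj_means[s], within_sd_frac * base)
      hrt <- max(hrt, 1)
      seed_se <- (base_cfg$seed + 7919L * s + 131L * e) %% .Machine$integer.max
      cfg <- base_cfg
      cfg$true_hrt_ms <- hrt
      cfg$seed <- as.integer(seed_se)
      cfg$n_vessels <- as.integer(vessels_per_exam)
      bundles[[length(bundles) + 1L]] <- list(
        subject_id = sprintf("S%d", s), exam_id = sprintf("E%d", e),
        cfg = cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%d", s), exam_id = sprintf("E%d", e),
        vessel_id = paste0("A", seq_len(vessels_per_exam)),
        true_hrt_ms = hrt)
    }
  }
  list(bundles = bundles, truth = do.call(rbind, rows),
       subject_means = subj_means)
}

#' Write a cohort of exam bundles to a directory tree
#'
#' @param cohort output of [generate_cohort()].
#' @param root_dir output root; bundles land in `root/subject/exam/` and the
#'   truth table in `root/cohort_truth.csv`.
#' @return `root_dir`, invisibly.
#' @export
write_cohort <- function(cohort, root_dir) {
  dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in cohort$bundles)
    write_exam_bundle(b$cfg, file.path(root_dir, b$subject_id, b$exam_id),
                      subject_id = b$subject_id, exam_id = b$exam_id)
  utils::write.csv(cohort$truth, file.path(root_dir, "cohort_truth.csv"),
                   row.names = FALSE)
  invisible(root_dir)
}
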