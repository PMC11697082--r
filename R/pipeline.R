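#' Analyze one exam held in memory
#'
#' Runs the full chain for every vessel: ECG resampling and R-peak detection,
#' optional rigid registration, subarea SNR extraction, fringe-washout
#' inversion into a velocity profile, pulse-arrival detection in heart-rate
#' bins, and cross-correlation HRT estimation. A failure in one vessel is
#' caught and reported; the remaining vessels are still processed.
#'
#' @param ecg an `ecg_trace`.
#' @param stack a `bscan_stack` (registered or not).
#' @param tracks a `vessel_track` or list of them.
#' @param cfg an `hrt_config`.
#' @param washout a `washout_params`; `NULL` derives it from the stack's scan
#'   parameters.
#' @param register run rigid registration first when the stack is
#'   unregistered (default TRUE).
#' @param max_rotation_deg rotation search range for registration (default 0,
#'   translation only).
#' @param passes registration refinement passes (default 1: sub-pixel phase
#'   correlation after the bootstrap pass is already well within the margin
#'   the subarea window leaves inside the vessel lumen).
#' @param ecg_rate_hz resampling rate for the ECG (default 125).
#' @param smooth_window envelope smoothing passed to [build_flow_profile()].
#' @param verbose message per-stage timings to stderr (default FALSE).
#' @return list of class `exam_result`: `r_peaks`, `rr_mean_ms`, `ecg_signal`,
#'   `transforms` (NULL if not registered here), and `vessels`, a named list
#'   with per-vessel `series`, `solutions`, `profile`, `arrivals`, `estimate`
#'   (or `error` message on failure).
#' @export
analyze_exam <- function(ecg, stack, tracks, cfg = hrt_config(),
                         washout = NULL, register = TRUE,
                         max_rotation_deg = 0, passes = 1L,
                         ecg_rate_hz = 125, smooth_window = 0L,
                         verbose = FALSE) {
  if (inherits(tracks, "vessel_track")) tracks <- list(tracks)
  names(tracks) <- vapply(tracks, `[[`, character(1), "vessel_id")
  if (is.null(washout)) washout <- washout_params_from_scan(stack$params)
  stage <- function(name, start) {
    if (verbose)
      message(sprintf("[%s] %.2f s", name, (proc.time() - start)[["elapsed"]]))
  }

  t0 <- proc.time()
  sig <- resample_ecg(ecg, ecg_rate_hz)
  r_peaks <- detect_r_peaks(sig)
  if (length(r_peaks$times_ms) < 2L)
    stop("fewer than 2 R-peaks detected in the ECG", call. = FALSE)
  rr <- mean_rr_ms(r_peaks)
  stage("ecg: resample + r-peaks", t0)

  transforms <- NULL
  t0 <- proc.time()
  if (!stack$registered && register) {
    reg <- register_stack(stack, max_rotation_deg = max_rotation_deg,
                          passes = passes)
    stack <- reg$stack
    transforms <- reg$transforms
    stage("registration", t0)
  } else if (!stack$registered) {
    stack$registered <- TRUE  # caller vouches for a drift-free stack
  }

  t0 <- proc.time()
  vessels <- lapply(tracks, function(track) {
    tryCatch({
      series <- extract_subarea_series(stack, track)
      fp <- build_flow_profile(series, washout, smooth_window = smooth_window)
      arrivals <- detect_pulse_arrivals(fp$profile, rr)
      est <- estimate_hrt(arrivals, r_peaks, cfg,
                          oct_span_ms = range(stack$timestamps_ms),
                          event_res_ms = stats::median(diff(stack$timestamps_ms)))
      list(series = series, solutions = fp$solutions, profile = fp$profile,
           arrivals = arrivals, estimate = est)
    }, error = function(e) list(error = conditionMessage(e)))
  })
  stage("vessels: subarea + washout + hrt", t0)
  config <- c(unclass(cfg),
              list(register = register, max_rotation_deg = max_rotation_deg,
                   passes = passes, ecg_rate_hz = ecg_rate_hz,
                   smooth_window = smooth_window,
                   clock_offset_ms = ecg$clock_offset_ms))
  structure(list(r_peaks = r_peaks, rr_mean_ms = rr, ecg_signal = sig,
                 transforms = transforms, vessels = vessels,
                 config = config),
            class = "exam_result")
}

#' @export
print.exam_result <- function(x, ...) {
  ok <- vapply(x$vessels, function(v) is.null(v$error), logical(1))
  cat(sprintf("<exam_result> %d/%d vessels analysed, RR %.0f ms\n",
              sum(ok), length(ok), x$rr_mean_ms))
  for (id in names(x$vessels)) {
    v <- x$vessels[[id]]
    if (is.null(v$error))
      cat(sprintf("  %s: HRT %.1f ms%s\n", id, v$estimate$hrt_ms,
                  if (v$estimate$is_outlier) " [outlier]" else ""))
    else cat(sprintf("  %s: ERROR %s\n", id, v$error))
  }
  invisible(x)
}

exam_result_json <- function(res) {
  list(
    config = res$config,
    rr_mean_ms = res$rr_mean_ms,
    r_peak_times_ms = res$r_peaks$times_ms,
    vessels = lapply(res$vessels, function(v) {
      if (!is.null(v$error)) return(list(error = v$error))
      list(hrt_ms = v$estimate$hrt_ms, offset_ms = v$estimate$offset_ms,
           global_offset_ms = v$estimate$global_offset_ms,
           is_outlier = v$estimate$is_outlier,
           arrival_times_ms = v$arrivals$times_ms)
    }))
}

#' Run one exam from files on disk
#'
#' Reads the ECG CSV, the stack container and the annotation CSV, analyses
#' every annotated vessel, and writes `results.json` plus per-vessel signal
#' panels and cross-correlation figures to `out_dir`.
#'
#' @param ecg_csv,stack_dir,annotations_csv input paths.
#' @param out_dir output directory; `NULL` skips writing.
#' @param clock_offset_ms applied to the ECG timestamps (default 0).
#' @param make_plots write PNG figures (default TRUE).
#' @param ... passed to [analyze_exam()].
#' @return an `exam_result`, invisibly.
#' @export
run_exam <- function(ecg_csv, stack_dir, annotations_csv, out_dir = NULL,
                     clock_offset_ms = 0, make_plots = TRUE, ...) {
  ecg <- read_ecg_csv(ecg_csv, clock_offset_ms = clock_offset_ms)
  stack <- read_stack(stack_dir)
  tracks <- read_annotations(annotations_csv)
  res <- analyze_exam(ecg, stack, tracks, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(exam_result_json(res),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    if (make_plots) {
      for (id in names(res$vessels)) {
        v <- res$vessels[[id]]
        if (!is.null(v$error)) next
        try({
          plot_exam_panels(res, id,
                           path = file.path(out_dir,
                                            sprintf("panels_%s.png", id)))
          plot_cross_correlation(v$estimate,
                                 path = file.path(out_dir,
                                                  sprintf("cc_%s.png", id)))
        }, silent = TRUE)
      }
    }
  }
  invisible(res)
}

#' Analyze a synthetic cohort in memory
#'
#' Generates every exam of a [generate_cohort()] design and runs
#' [analyze_exam()] on it, without touching disk. One record is produced per
#' vessel; vessels that fail are skipped.
#'
#' @param cohort output of [generate_cohort()].
#' @param ... passed to [analyze_exam()].
#' @return list with `records` (a `cohort_records`), `offsets_ms`
#'   (unrestricted argmax offsets) and `report` (a `cov_report`).
#' @export
analyze_cohort <- function(cohort, ...) {
  rows <- list(); offsets <- numeric(0)
  for (b in cohort$bundles) {
    ex <- generate_exam(b$cfg)
    res <- suppressWarnings(analyze_exam(ex$ecg, ex$stack, ex$tracks, ...))
    for (id in names(res$vessels)) {
      v <- res$vessels[[id]]
      if (!is.null(v$error)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = b$subject_id, exam_id = b$exam_id, vessel_id = id,
        hrt_ms = v$estimate$hrt_ms, is_outlier = v$estimate$is_outlier)
      offsets <- c(offsets, v$estimate$global_offset_ms)
    }
  }
  r <- do.call(rbind, rows)
  records <- cohort_records(r$subject_id, r$exam_id, r$vessel_id, r$hrt_ms,
                            r$is_outlier)
  list(records = records, offsets_ms = offsets, report = cov_report(records))
}

find_bundles <- function(root_dir) {
  ecgs <- list.files(root_dir, pattern = "^ecg\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  dirname(ecgs)
}

#' Run every exam bundle under a directory tree
#'
#' Locates bundles (directories containing `ecg.csv`, `stack/`,
#' `annotations.csv`), runs [run_exam()] on each, aggregates one record per
#' vessel, and computes the coefficient-of-variation report (outliers
#' excluded) plus a 50 ms-bin histogram of the unrestricted cross-correlation
#' argmax offsets. A failing exam is reported and skipped.
#'
#' @param root_dir bundle tree root.
#' @param out_dir output directory; `NULL` skips writing.
#' @param make_plots write the histogram figure (default TRUE).
#' @param ... passed to [analyze_exam()].
#' @return list with `records` (a `cohort_records` data.frame), `report`
#'   (a `cov_report`), `offsets_ms` (unrestricted argmax offsets) and
#'   `failures`.
#' @export
run_cohort <- function(root_dir, out_dir = NULL, make_plots = TRUE, ...) {
  dirs <- find_bundles(root_dir)
  if (!length(dirs)) stop("no exam bundles found under ", root_dir,
                          call. = FALSE)
  rows <- list(); offsets <- numeric(0); failures <- list()
  for (d in dirs) {
    ids <- tryCatch(
      jsonlite::read_json(file.path(d, "bundle.json"), simplifyVector = TRUE),
      error = function(e) list(subject_id = basename(dirname(d)),
                               exam_id = basename(d)))
    res <- tryCatch(
      run_exam(file.path(d, "ecg.csv"), file.path(d, "stack"),
               file.path(d, "annotations.csv"), out_dir = NULL, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[d]] <- conditionMessage(res)
      next
    }
    for (id in names(res$vessels)) {
      v <- res$vessels[[id]]
      if (!is.null(v$error)) {
        failures[[paste(d, id, sep = ":")]] <- v$error
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids$subject_id, exam_id = ids$exam_id, vessel_id = id,
        hrt_ms = v$estimate$hrt_ms, is_outlier = v$estimate$is_outlier)
      offsets <- c(offsets, v$estimate$global_offset_ms)
    }
  }
  if (!length(rows)) stop("no vessel produced an HRT estimate", call. = FALSE)
  records <- do.call(rbind, rows)
  records <- cohort_records(records$subject_id, records$exam_id,
                            records$vessel_id, records$hrt_ms,
                            records$is_outlier)
  report <- cov_report(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "records.jsonl"), "w")
    for (i in seq_len(nrow(records)))
      writeLines(as.character(jsonlite::toJSON(as.list(records[i, ]),
                                               auto_unbox = TRUE,
                                               digits = NA)), con)
    close(con)
    jsonlite::write_json(unclass(report), file.path(out_dir, "cov_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (make_plots)
      try(plot_offset_histogram(offsets,
                                path = file.path(out_dir,
                                                 "offset_histogram.png")),
          silent = TRUE)
  }
  list(records = records, report = report, offsets_ms = offsets,
       failures = failures)
}
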