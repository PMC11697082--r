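#' Fringe-washout model parameters
#'
#' Axial motion of scatterers during the integration time washes out the
#' interference fringes: the SNR of a uniformly moving scatterer drops as
#' `sinc^2(k0 * dz)` with `k0 = 2 * pi / lambda` the central wavenumber and
#' `dz = n * v * t` the optical path change over the integration time.
#'
#' @param wavelength_m central wavelength (default 880e-9).
#' @param refractive_index bulk refractive index (default 1.36).
#' @param integration_time_s per-A-scan integration time in seconds
#'   (44.8e-6 at the 20 kHz nominal line rate, 11.2e-6 at 85 kHz).
#' @param n_branches maximum number of inversion branches to return
#'   (default 5).
#' @return An object of class `washout_params` with the derived `k0`
#'   (rad/m).
#' @export
washout_params <- function(wavelength_m = 880e-9, refractive_index = 1.36,
                           integration_time_s = 44.8e-6, n_branches = 5L) {
  if (wavelength_m <= 0 || refractive_index <= 0 || integration_time_s <= 0)
    stop("wavelength, refractive index and integration time must be positive",
         call. = FALSE)
  n_branches <- as.integer(n_branches)
  if (n_branches < 1L) stop("n_branches must be >= 1", call. = FALSE)
  structure(list(k0 = 2 * pi / wavelength_m, n = refractive_index,
                 t = integration_time_s, n_branches = n_branches,
                 wavelength_m = wavelength_m),
            class = "washout_params")
}

#' @rdname washout_params
#' @param params a `scan_params`.
#' @export
washout_params_from_scan <- function(params, n_branches = 5L) {
  washout_params(params$wavelength_m, params$refractive_index,
                 params$integration_time_s, n_branches)
}

sinc2 <- function(x) ifelse(x == 0, 1, (sin(x) / x)^2)
dsinc2 <- function(x)
  ifelse(x == 0, 0, 2 * sin(x) * (x * cos(x) - sin(x)) / x^3)

# dimensionless washout argument x = k0 * n * v * t for v in mm/s
velocity_to_x <- function(v_mm_s, params)
  v_mm_s / 1000 * params$k0 * params$n * params$t
x_to_velocity <- function(x, params)
  x / (params$k0 * params$n * params$t) * 1000

#' Forward fringe-washout relation
#'
#' SNR drop caused by an axial velocity `v`:
#' `sinc^2(k0 * n * v * t)`, with the removable singularity at `v = 0`
#' defined as 1.
#'
#' @param v axial velocity in mm/s, `>= 0` (vectorised).
#' @param params a `washout_params`.
#' @return SNR drop in \[0, 1\].
#' @export
forward_washout <- function(v, params) {
  if (any(v < 0)) stop("velocity must be non-negative", call. = FALSE)
  sinc2(velocity_to_x(v, params))
}

root_in <- function(d, lower, upper, flo, fhi) {
  r <- stats::uniroot(function(x) sinc2(x) - d, lower = lower, upper = upper,
                      f.lower = flo, f.upper = fhi, tol = 1e-13,
                      maxiter = 1000L)$root
  # Newton polish toward |x error| ~ 1e-12 where well-conditioned
  for (it in 1:3) {
    g <- dsinc2(r)
    if (!is.finite(g) || abs(g) < 1e-8) break
    step <- (sinc2(r) - d) / g
    r2 <- r - step
    if (r2 <= lower || r2 >= upper) break
    r <- r2
  }
  r
}

#' Invert the fringe-washout relation into candidate velocities
#'
#' `sinc^2` is not injective, so an observed SNR drop maps to several
#' candidate axial velocities - the numerical solution index (NSI) enumerates
#' them. Branch 0 is the unique root in the principal lobe `x in [0, pi)`;
#' each side lobe `(m*pi, (m+1)*pi)` whose peak exceeds the observed drop
#' contributes its falling-flank root (so that velocity increases with NSI),
#' or both flanks with `branch_mode = "both"`. Roots are bracketed by
#' bisection to an absolute tolerance of 1e-12 in the dimensionless argument.
#'
#' @param snr_drop observed SNR drop, scalar in (0, 1\].
#' @param params a `washout_params`; `n_branches` caps the lobes examined.
#' @param branch_mode `"falling"` (default, one root per lobe) or `"both"`.
#' @return data.frame with columns `nsi` (0-based) and `v` (mm/s), sorted by
#'   increasing velocity.
#' @export
invert_washout <- function(snr_drop, params, branch_mode = c("falling", "both")) {
  branch_mode <- match.arg(branch_mode)
  if (!is.finite(snr_drop) || snr_drop <= 0 || snr_drop > 1)
    stop("snr_drop must lie in (0, 1]", call. = FALSE)
  if (snr_drop == 1)
    return(data.frame(nsi = 0L, v = 0))
  xs <- root_in(snr_drop, 0, pi, 1 - snr_drop, -snr_drop)
  for (m in seq_len(params$n_branches - 1L)) {
    lobe <- c(m * pi, (m + 1) * pi)
    pk <- stats::optimize(sinc2, lobe, maximum = TRUE, tol = 1e-12)
    if (pk$objective <= snr_drop) break  # lobe peaks only get lower
    if (branch_mode == "both")
      xs <- c(xs, root_in(snr_drop, lobe[1], pk$maximum,
                          -snr_drop, pk$objective - snr_drop))
    xs <- c(xs, root_in(snr_drop, pk$maximum, lobe[2],
                        pk$objective - snr_drop, -snr_drop))
  }
  xs <- sort(xs)
  data.frame(nsi = seq_along(xs) - 1L, v = x_to_velocity(xs, params))
}

#' Build the multi-branch velocity profile from a subarea SNR series
#'
#' Inverts each frame's SNR drop into its candidate velocities, takes the
#' per-frame maximal-branch velocity as the envelope, and differentiates the
#' envelope with central differences on the actual (possibly uneven) frame
#' timestamps (one-sided at the endpoints).
#'
#' @param series a `subarea_series`.
#' @param params a `washout_params`.
#' @param smooth_window optional odd moving-average window (frames) applied to
#'   the envelope before differentiation; 0 (default) disables smoothing.
#' @param branch_mode passed to [invert_washout()].
#' @return list with `solutions` (data.frame `frame`, `timestamp_ms`, `nsi`,
#'   `v`) and `profile`, a `flow_profile` with `timestamps_ms`, `envelope_v`
#'   (mm/s) and `gradient` (mm/s per ms).
#' @export
build_flow_profile <- function(series, params, smooth_window = 0L,
                               branch_mode = "falling") {
  stopifnot(inherits(series, "subarea_series"))
  d <- series$snr_drop
  if (any(!is.finite(d) | d <= 0 | d > 1))
    stop("snr_drop values must lie in (0, 1]; clip upstream", call. = FALSE)
  t_ms <- series$timestamps_ms
  sols <- lapply(seq_along(d), function(i) {
    s <- invert_washout(d[i], params, branch_mode)
    data.frame(frame = i - 1L, timestamp_ms = t_ms[i], nsi = s$nsi, v = s$v)
  })
  sols <- do.call(rbind, sols)
  env <- vapply(split(sols$v, sols$frame), max, numeric(1))
  env <- as.numeric(env[order(as.integer(names(env)))])
  if (smooth_window >= 3L) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- as.numeric(stats::filter(env, k, sides = 2))
    env <- ifelse(is.na(sm), env, sm)
  }
  n <- length(env)
  grad <- numeric(n)
  if (n >= 2L) {
    grad[1] <- (env[2] - env[1]) / (t_ms[2] - t_ms[1])
    grad[n] <- (env[n] - env[n - 1]) / (t_ms[n] - t_ms[n - 1])
    if (n >= 3L) {
      i <- 2:(n - 1)
      grad[i] <- (env[i + 1] - env[i - 1]) / (t_ms[i + 1] - t_ms[i - 1])
    }
  }
  profile <- structure(list(timestamps_ms = t_ms, envelope_v = env,
                            gradient = grad, vessel_id = series$vessel_id),
                       class = "flow_profile")
  list(solutions = sols, profile = profile)
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> %d frames, envelope %.2f-%.2f mm/s\n",
              length(x$envelope_v), min(x$envelope_v), max(x$envelope_v)))
  invisible(x)
}

#' Detect pulse-arrival times from a flow profile
#'
#' The sharpest rise of the flow velocity marks the arrival of the pulse wave
#' at the retina. The profile's time span is partitioned into consecutive
#' bins of one mean cardiac cycle (`rr_ms`) starting at the first frame;
#' within each bin containing at least 3 frames the frame of maximal velocity
#' gradient is emitted as one pulse-arrival event (ties break toward the
#' earlier frame).
#'
#' @param profile a `flow_profile`.
#' @param rr_ms mean RR interval from the ECG, ms.
#' @return a `peak_train` of kind `"pulse_arrival"`.
#' @export
detect_pulse_arrivals <- function(profile, rr_ms) {
  stopifnot(inherits(profile, "flow_profile"))
  if (!is.finite(rr_ms) || rr_ms <= 0)
    stop("rr_ms must be positive", call. = FALSE)
  t_ms <- profile$timestamps_ms
  if (!length(t_ms)) stop("empty flow profile", call. = FALSE)
  bin <- floor((t_ms - t_ms[1]) / rr_ms)
  events <- vapply(split(seq_along(t_ms), bin), function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    t_ms[idx[which.max(profile$gradient[idx])]]
  }, numeric(1))
  peak_train(sort(events[!is.na(events)]), kind = "pulse_arrival")
}
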