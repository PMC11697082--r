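#' Apply a rigid transform to an image
#'
#' The transform rotates the image by `theta_deg` about the image centre and
#' then translates it by `(dx, dy)` pixels (x = lateral column, y = axial
#' row). Resampling is bilinear; pixels mapped from outside the support are
#' zero-filled, producing the familiar black borders of registered B-scans.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param dx,dy translation in pixels.
#' @param theta_deg rotation in degrees (counter-clockwise in pixel axes).
#' @return transformed matrix of the same size.
#' @export
rigid_warp <- function(img, dx = 0, dy = 0, theta_deg = 0) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- theta_deg * pi / 180
  X <- matrix(rep(seq_len(w), each = h), nrow = h)
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)
  # inverse mapping: rotate by -theta about centre after removing translation
  ux <- X - dx - cx; uy <- Y - dy - cy
  qx <- cos(th) * ux + sin(th) * uy + cx
  qy <- -sin(th) * ux + cos(th) * uy + cy
  x0 <- floor(qx); y0 <- floor(qy)
  wx <- qx - x0; wy <- qy - y0
  out <- matrix(0, h, w)
  valid <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  if (any(valid)) {
    ix0 <- x0[valid]; iy0 <- y0[valid]; fx <- wx[valid]; fy <- wy[valid]
    g <- function(xi, yi) img[(xi - 1) * h + yi]
    out[valid] <-
      (1 - fx) * (1 - fy) * g(ix0, iy0) +
      fx * (1 - fy) * g(ix0 + 1, iy0) +
      (1 - fx) * fy * g(ix0, iy0 + 1) +
      fx * fy * g(ix0 + 1, iy0 + 1)
  }
  out
}

invert_transform <- function(tf) {
  th <- tf$theta_deg * pi / 180
  list(dx = -(cos(th) * tf$dx + sin(th) * tf$dy),
       dy = -(-sin(th) * tf$dx + cos(th) * tf$dy),
       theta_deg = -tf$theta_deg)
}

# Phase-correlation translation estimate with parabolic subpixel fit.
# Returns the shift (dx, dy) such that frame ~ ref translated by (dx, dy),
# plus the correlation peak height as a match score. Phase correlation keeps
# a sharp peak in the presence of the zero-filled borders that large drifts
# leave behind, where plain cross-correlation is biased by the border bands.
estimate_translation <- function(ref, frame, max_shift = NULL) {
  a <- ref - mean(ref); b <- frame - mean(frame)
  h <- nrow(a); w <- ncol(a)
  X <- Conj(stats::fft(a)) * stats::fft(b)
  mx <- max(Mod(X))
  if (mx == 0) return(list(dx = 0, dy = 0, score = 0))
  cc <- Re(stats::fft(X / (Mod(X) + 1e-9 * mx), inverse = TRUE)) / length(a)
  # cc[1 + m, 1 + k] peaks where frame ~ ref shifted by (k, m), wrapped
  sy <- c(0:(h - 1)); sy[sy > h / 2] <- sy[sy > h / 2] - h
  sx <- c(0:(w - 1)); sx[sx > w / 2] <- sx[sx > w / 2] - w
  if (!is.null(max_shift)) {
    bad <- outer(abs(sy) > max_shift, rep(TRUE, w)) |
      outer(rep(TRUE, h), abs(sx) > max_shift)
    cc[bad] <- -Inf
  }
  pk <- arrayInd(which.max(cc), dim(cc))
  py <- pk[1]; px <- pk[2]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (is.finite(cm) && is.finite(cp) && den < 0) 0.5 * (cm - cp) / den else 0
  }
  ddx <- para(cc[py, wrap(px - 1, w)], cc[py, px], cc[py, wrap(px + 1, w)])
  ddy <- para(cc[wrap(py - 1, h), px], cc[py, px], cc[wrap(py + 1, h), px])
  list(dx = sx[px] + ddx, dy = sy[py] + ddy, score = cc[py, px])
}

# masked real-space normalised correlation between the reference and the
# frame warped back by the inverse of the candidate transform; smooth in the
# angle where the phase-correlation peak height is not
ncc_backwarped <- function(ref, frame, tf) {
  inv <- invert_transform(tf)
  back <- rigid_warp(frame, inv$dx, inv$dy, inv$theta_deg)
  mask <- back > 0 & ref > 0
  if (sum(mask) < 64) return(-1)
  x <- back[mask] - mean(back[mask]); y <- ref[mask] - mean(ref[mask])
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) return(-1)
  sum(x * y) / den
}

register_one <- function(ref, frame, max_shift, max_rotation_deg,
                         coarse_step_deg = 0.25) {
  if (max_rotation_deg <= 0) {
    e <- estimate_translation(ref, frame, max_shift)
    return(list(dx = e$dx, dy = e$dy, theta_deg = 0, score = e$score))
  }
  eval_angle <- function(a) {
    unrot <- rigid_warp(frame, 0, 0, -a)
    e <- estimate_translation(ref, unrot, max_shift)
    # the shift is measured in the unrotated frame; the motion translates by
    # R(a) * e under the rotate-then-translate convention
    th <- a * pi / 180
    tf <- list(dx = cos(th) * e$dx - sin(th) * e$dy,
               dy = sin(th) * e$dx + cos(th) * e$dy,
               theta_deg = a)
    tf$score <- ncc_backwarped(ref, frame, tf)
    tf
  }
  angles <- seq(-max_rotation_deg, max_rotation_deg, by = coarse_step_deg)
  scores <- vapply(angles, function(a) eval_angle(a)$score, numeric(1))
  a0 <- angles[which.max(scores)]
  opt <- stats::optimize(function(a) eval_angle(a)$score,
                         lower = max(-max_rotation_deg, a0 - coarse_step_deg),
                         upper = min(max_rotation_deg, a0 + coarse_step_deg),
                         maximum = TRUE, tol = 0.005)
  best <- eval_angle(opt$maximum)
  best
}

#' Estimate the rigid transform between two images
#'
#' Single-pair version of the stack registration: returns the motion
#' (`dx`, `dy`, `theta_deg`, plus a match `score`) that maps the reference
#' onto the frame.
#'
#' @param ref,frame numeric matrices of identical size.
#' @param max_shift_px translation search radius.
#' @param max_rotation_deg rotation search half-range; 0 for translation
#'   only.
#' @return list with `dx`, `dy`, `theta_deg`, `score`.
#' @export
register_frame <- function(ref, frame, max_shift_px = 15,
                           max_rotation_deg = 1.5) {
  stopifnot(is.matrix(ref), is.matrix(frame), all(dim(ref) == dim(frame)))
  register_one(ref, frame, max_shift_px, max_rotation_deg)
}

#' Rigidly register a B-scan stack
#'
#' Aligns every frame to the average of the first `n_reference` frames with a
#' rigid transform (translation, optionally plus in-plane rotation), using
#' FFT cross-correlation with parabolic sub-pixel refinement and, when
#' rotation is enabled, a coarse-to-fine angle search. A second pass rebuilds
#' the reference from the aligned leading frames (much sharper than the raw
#' average when drift is large) and re-registers.
#'
#' The absolute pose of a stack is unobservable - only frame-to-frame motion
#' is - so the estimated transforms are re-centred after each pass so that the
#' mean transform over the reference window is the identity; this anchors the
#' output gauge at the mean pose of the frames that define the reference.
#'
#' @param stack an unregistered `bscan_stack`.
#' @param n_reference frames averaged into the reference (default 10, capped
#'   at the stack length).
#' @param max_shift_px translation search radius (default 15).
#' @param max_rotation_deg rotation search half-range in degrees; 0 (default)
#'   estimates translation only. Eye-motion in these acquisitions is
#'   predominantly translational; enable rotation when needed.
#' @param passes number of register/re-reference passes (default 2).
#' @return list with `stack` (the registered `bscan_stack`) and `transforms`,
#'   a data.frame with one row per frame (`dx`, `dy`, `theta_deg`, `score`)
#'   giving the estimated motion of each frame relative to the reference pose.
#' @export
register_stack <- function(stack, n_reference = 10L, max_shift_px = 15,
                           max_rotation_deg = 0, passes = 2L) {
  stopifnot(inherits(stack, "bscan_stack"))
  n <- length(stack$frames)
  n_reference <- min(as.integer(n_reference), n)
  ref <- build_reference(stack, n_reference)
  if (all(ref == 0)) stop("degenerate all-zero reference image", call. = FALSE)
  # bootstrap pass against the sharp first frame: the raw first-ten average is
  # blurred when drift is large, which degrades the correlation peak; aligning
  # to frame 1 first lets the averaged reference be rebuilt sharp
  est <- lapply(stack$frames, function(f)
    register_one(stack$frames[[1]], f, max_shift_px, max_rotation_deg))
  for (pass in seq_len(max(1L, as.integer(passes)))) {
    aligned_head <- lapply(seq_len(n_reference), function(i) {
      inv <- invert_transform(est[[i]])
      rigid_warp(stack$frames[[i]], inv$dx, inv$dy, inv$theta_deg)
    })
    ref <- Reduce(`+`, aligned_head) / n_reference
    est <- lapply(stack$frames, function(f)
      register_one(ref, f, max_shift_px, max_rotation_deg))
    # gauge fix: mean transform over the reference window -> identity
    mdx <- mean(vapply(est[seq_len(n_reference)], `[[`, numeric(1), "dx"))
    mdy <- mean(vapply(est[seq_len(n_reference)], `[[`, numeric(1), "dy"))
    mth <- mean(vapply(est[seq_len(n_reference)], `[[`, numeric(1),
                       "theta_deg"))
    est <- lapply(est, function(e) {
      e$dx <- e$dx - mdx; e$dy <- e$dy - mdy; e$theta_deg <- e$theta_deg - mth
      e
    })
  }
  aligned <- lapply(seq_len(n), function(i) {
    inv <- invert_transform(est[[i]])
    out <- rigid_warp(stack$frames[[i]], inv$dx, inv$dy, inv$theta_deg)
    pmin(pmax(out, 0), 1)
  })
  out_stack <- bscan_stack(aligned, stack$timestamps_ms, stack$max_raw,
                           stack$quality_db, stack$params, registered = TRUE)
  transforms <- data.frame(
    dx = vapply(est, `[[`, numeric(1), "dx"),
    dy = vapply(est, `[[`, numeric(1), "dy"),
    theta_deg = vapply(est, `[[`, numeric(1), "theta_deg"),
    score = vapply(est, `[[`, numeric(1), "score"))
  list(stack = out_stack, transforms = transforms)
}
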