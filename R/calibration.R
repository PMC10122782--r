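#' Paired point sets for spatial calibration
#'
#' Corresponding 3D point measurements in two coordinate frames (e.g. tracker
#' space and CT/PET image space); correspondence is positional. At least three
#' non-collinear points are required for a unique rigid fit; six paired
#' measurements are the default calibration protocol.
#'
#' @param points_a,points_b n x 3 matrices (mm), row i of `points_a`
#'   corresponding to row i of `points_b`.
#' @return An object of class `paired_points`.
#' @export
paired_points <- function(points_a, points_b) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  if (nrow(points_a) != nrow(points_b)) stop("point sets have different lengths")
  if (nrow(points_a) < 3L) stop("need at least 3 paired points")
  if (ncol(points_a) != 3L || ncol(points_b) != 3L) stop("points must be 3D")
  if (!all(is.finite(points_a)) || !all(is.finite(points_b))) {
    stop("points must be finite")
  }
  for (p in list(points_a, points_b)) {
    c0 <- sweep(p, 2, colMeans(p))
    if (sum(svd(c0)$d > 1e-9 * max(1, max(abs(c0)))) < 2L) {
      stop("degenerate point set: points are collinear")
    }
  }
  structure(list(points_a = points_a, points_b = points_b),
            class = "paired_points")
}

#' Rigid point-set registration by SVD (Arun/Kabsch)
#'
#' Finds the rigid transform mapping `points_a` onto `points_b` in the
#' least-squares sense: centroids are removed, the covariance matrix is
#' decomposed by SVD, and the rotation is `V diag(1, 1, det(VU')) U'` so a
#' reflection is never returned even for noisy or mirrored data. Exact to
#' machine precision on noise-free data.
#'
#' @param ps a `paired_points` object.
#' @return A list with `transform` (a `rigid_transform` such that
#'   `apply_rigid(transform, points_a)` approximates `points_b`) and
#'   `residual_rms` (mm).
#' @examples
#' a <- matrix(rnorm(18), 6, 3)
#' tr <- compose(rt_rotation_z(20), rt_translation(c(40, 0, 0)))
#' fit <- fit_rigid_svd(paired_points(a, apply_rigid(tr, a)))
#' fit$residual_rms
#' @export
fit_rigid_svd <- function(ps) {
  stopifnot(inherits(ps, "paired_points"))
  a <- ps$points_a; b <- ps$points_b
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)            # covariance of the paired sets
  s <- svd(h)
  d <- det(s$v %*% t(s$u))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(r %*% ca)
  tr <- rigid_transform(r, t)
  res <- apply_rigid(tr, a) - b
  list(transform = tr, residual_rms = sqrt(mean(rowSums(res^2))))
}

#' Global tracker-to-image transform chain
#'
#' Chains the spatial calibration `mc` (tracker space to image space), the
#' reference target pose `m_ref` and the current target pose `m_t` into the
#' global transform `L = mc o m_ref o m_t^-1 o mc^-1`, which maps image-space
#' points at the current pose back to the reference pose. With the target at
#' its reference pose (`m_t = m_ref`) the chain collapses to the identity.
#'
#' @param mc calibration transform (tracker -> image space).
#' @param m_ref reference pose of the target in tracker space.
#' @param m_t current pose of the target in tracker space.
#' @return A `rigid_transform`.
#' @export
global_transform <- function(mc, m_ref, m_t) {
  compose(compose(mc, m_ref), compose(invert(m_t), invert(mc)))
}

#' Hand-eye calibration from relative motions
#'
#' Recovers the fixed transform `X` relating two spaces from paired relative
#' motions: `A_i X = X B_i` where `A_i` are relative motions observed in space
#' a and `B_i` the same motions observed in space b. The rotation is solved by
#' aligning the rotation axes (angle-weighted SVD fit), then the translation
#' follows from linear least squares on `(R_Ai - I) t_X = R_X t_Bi - t_Ai`.
#' Rotations about at least two independent axes are required; otherwise the
#' problem is under-determined and an error is raised.
#'
#' @param motions_a,motions_b lists of `rigid_transform` relative motions.
#' @return A list with `transform` (X) and `residual` (RMS of
#'   `A_i X - X B_i` over all matrix entries).
#' @export
calibrate_relative <- function(motions_a, motions_b) {
  if (length(motions_a) != length(motions_b)) stop("motion lists differ in length")
  if (length(motions_a) < 2L) stop("need at least 2 relative motion pairs")
  axang <- function(t) {
    r <- t$rotation
    ang <- acos(pmin(pmax((sum(diag(r)) - 1) / 2, -1), 1))
    if (ang < 1e-12) return(list(axis = c(0, 0, 0), angle = 0))
    ax <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / (2 * sin(ang))
    list(axis = ax, angle = ang)
  }
  aa <- lapply(motions_a, axang); bb <- lapply(motions_b, axang)
  wts <- vapply(aa, function(z) z$angle, numeric(1))
  use <- wts > 1e-9
  if (sum(use) < 2L) stop("under-determined: need rotations about >= 2 independent axes")
  axes_a <- t(vapply(aa[use], function(z) z$axis, numeric(3))) * wts[use]
  axes_b <- t(vapply(bb[use], function(z) z$axis, numeric(3))) * wts[use]
  if (sum(svd(axes_a)$d > 1e-9 * max(abs(axes_a))) < 2L) {
    stop("under-determined: all rotations share a single axis")
  }
  # R_X aligns axes of B onto axes of A: axis_a = R_X axis_b
  h <- crossprod(axes_b, axes_a)
  s <- svd(h)
  d <- det(s$v %*% t(s$u))
  rx <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  # translation least squares over all pairs
  lhs <- do.call(rbind, lapply(motions_a, function(a) a$rotation - diag(3)))
  rhs <- unlist(Map(function(a, b) as.numeric(rx %*% b$translation) - a$translation,
                    motions_a, motions_b))
  tx <- as.numeric(stats::lm.fit(lhs, rhs)$coefficients)
  tx[is.na(tx)] <- 0
  x <- rigid_transform(rx, tx)
  res <- vapply(seq_along(motions_a), function(i) {
    m <- rt_to_matrix(compose(motions_a[[i]], x)) -
      rt_to_matrix(compose(x, motions_b[[i]]))
    sqrt(mean(m^2))
  }, numeric(1))
  list(transform = x, residual = sqrt(mean(res^2)))
}

#' Pulse train on the scanner clock
#'
#' Synchronisation pulses injected into the list-mode stream: a start pattern
#' followed by periodic pulses used to estimate and remove clock offset and
#' drift between the tracker and the scanner.
#'
#' @param pulse_times strictly increasing pulse timestamps (ms, scanner clock).
#' @param start_pattern_length number of leading pulses forming the start
#'   pattern (they mark frame 1 and are excluded from the drift fit).
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(pulse_times, start_pattern_length = 0L) {
  pulse_times <- as.numeric(pulse_times)
  if (any(diff(pulse_times) <= 0)) stop("pulse times must be strictly increasing")
  stopifnot(start_pattern_length >= 0, start_pattern_length <= length(pulse_times))
  structure(list(pulse_times = pulse_times,
                 start_pattern_length = as.integer(start_pattern_length)),
            class = "pulse_train")
}

#' Align the tracker time base onto the scanner clock
#'
#' Periodic pulses recorded on the scanner clock correspond to every k-th
#' tracker frame (k inferred from the period ratio). A least-squares fit of
#' `pulse_time = offset + (1 + drift) * frame_time` estimates the clock offset
#' and at most a linear drift, the minimal model under which "no time drift"
#' is testable.
#'
#' @param pulses a `pulse_train`.
#' @param frame_times_ms strictly increasing tracker frame times (ms, tracker
#'   clock).
#' @return A list with `offset_ms`, `drift_ppm`, `residual_rms_ms` and the
#'   pulse-to-frame `stride`.
#' @export
align_timebases <- function(pulses, frame_times_ms) {
  stopifnot(inherits(pulses, "pulse_train"))
  frame_times_ms <- as.numeric(frame_times_ms)
  if (any(diff(frame_times_ms) <= 0)) stop("frame times must be strictly increasing")
  p <- pulses$pulse_times
  if (pulses$start_pattern_length > 0) {
    p <- p[-seq_len(pulses$start_pattern_length)]
  }
  if (length(p) < 2L) stop("need at least 2 periodic pulses after the start pattern")
  fper <- stats::median(diff(frame_times_ms))
  stride <- max(1L, as.integer(round(stats::median(diff(p)) / fper)))
  idx <- seq(1L, by = stride, length.out = length(p))
  if (max(idx) > length(frame_times_ms)) {
    idx <- idx[idx <= length(frame_times_ms)]
    p <- p[seq_along(idx)]
  }
  if (length(p) < 2L) stop("pulse train extends beyond the tracked frames")
  f <- frame_times_ms[idx]
  fit <- stats::lm.fit(cbind(1, f), p)
  offset <- fit$coefficients[[1]]
  drift <- fit$coefficients[[2]] - 1
  res <- sqrt(mean(fit$residuals^2))
  if (res > fper / 2) {
    warning("time-base residual exceeds half a frame period; correspondence may be wrong")
  }
  list(offset_ms = offset, drift_ppm = drift * 1e6, residual_rms_ms = res,
       stride = stride)
}

#' Map tracker frame times onto the scanner/event clock
#'
#' @param frame_times_ms tracker frame times (ms).
#' @param sync result of [align_timebases()], or NULL for identical clocks.
#' @return Frame times on the scanner clock (ms).
#' @export
apply_timebase <- function(frame_times_ms, sync = NULL) {
  if (is.null(sync)) return(frame_times_ms)
  sync$offset_ms + (1 + sync$drift_ppm * 1e-6) * frame_times_ms
}
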