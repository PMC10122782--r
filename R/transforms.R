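#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation in millimetres. All motion,
#' calibration and line-of-response repositioning in the package is expressed
#' through this algebra. The in-plane reconstruction geometry is 2D but
#' transforms are kept fully 3D so that the calibration chain is exercised in
#' three dimensions.
#'
#' @param rotation 3x3 orthonormal rotation matrix (dimensionless).
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' t1 <- rt_translation(c(0.66, 1.04, 0.83))
#' apply_rigid(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  }
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_transform components must be finite")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal (R'R != I within 1e-9)")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det = +1); reflections are not rigid motions")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation (mm):", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` leaving every point fixed.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Pure translation
#' @param t length-3 translation (mm); length-2 input is padded with z = 0.
#' @return A `rigid_transform`.
#' @export
rt_translation <- function(t) {
  if (length(t) == 2L) t <- c(t, 0)
  rigid_transform(diag(3), t)
}

#' Elementary rotations about a coordinate axis
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return A `rigid_transform` rotating about the isocenter.
#' @export
rt_rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(rbind(c(cos(a), -sin(a), 0),
                        c(sin(a),  cos(a), 0),
                        c(0, 0, 1)))
}

#' @rdname rt_rotation_z
#' @export
rt_rotation_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(rbind(c(1, 0, 0),
                        c(0, cos(a), -sin(a)),
                        c(0, sin(a),  cos(a))))
}

#' @rdname rt_rotation_z
#' @export
rt_rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(rbind(c(cos(a), 0, sin(a)),
                        c(0, 1, 0),
                        c(-sin(a), 0, cos(a))))
}

#' Build a transform from Euler angles (Z.Y.X intrinsic) and a translation
#'
#' Angles follow the file-format convention used throughout the package:
#' the rotation matrix is `Rz(rz) %*% Ry(ry) %*% Rx(rx)` (intrinsic Z.Y.X),
#' angles in degrees. Euler angles are accepted only at I/O boundaries; the
#' algebra itself works on matrices to avoid gimbal ambiguity.
#'
#' @param tx,ty,tz translation components (mm).
#' @param rx,ry,rz Euler angles (degrees).
#' @return A `rigid_transform`.
#' @export
rt_from_euler <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  r <- rt_rotation_z(rz)$rotation %*% rt_rotation_y(ry)$rotation %*%
    rt_rotation_x(rx)$rotation
  rigid_transform(r, c(tx, ty, tz))
}

#' Recover Euler angles (Z.Y.X intrinsic, degrees) and translation
#'
#' Inverse of [rt_from_euler()] away from gimbal lock (`|ry| = 90` degrees).
#'
#' @param t a `rigid_transform`.
#' @return One-row tibble with columns `tx, ty, tz, rx, ry, rz`.
#' @export
rt_to_euler <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  r <- t$rotation
  ry <- asin(-r[3, 1])
  if (abs(cos(ry)) < 1e-9) {
    # gimbal lock: fold rx into rz
    rz <- atan2(-r[1, 2], r[2, 2])
    rx <- 0
  } else {
    rz <- atan2(r[2, 1], r[1, 1])
    rx <- atan2(r[3, 2], r[3, 3])
  }
  tibble::tibble(tx = t$translation[1], ty = t$translation[2],
                 tz = t$translation[3],
                 rx = rx * 180 / pi, ry = ry * 180 / pi, rz = rz * 180 / pi)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points length-3 numeric vector or n x 3 matrix of points (mm);
#'   n x 2 input is treated as in-plane points with z = 0 and returned as n x 2.
#' @return Transformed points, same shape as the input.
#' @export
apply_rigid <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, nrow = 1) else as.matrix(points)
  two_d <- ncol(p) == 2L
  if (two_d) p <- cbind(p, 0)
  if (ncol(p) != 3L) stop("points must be 3-vectors (or in-plane 2-vectors)")
  if (!all(is.finite(p))) stop("non-finite input point")
  out <- p %*% t(t$rotation) + matrix(t$translation, nrow(p), 3, byrow = TRUE)
  if (two_d) out <- out[, 1:2, drop = FALSE]
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`:
#' `apply_rigid(compose(a, b), p) == apply_rigid(a, apply_rigid(b, p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse transform: `compose(t, invert(t))` is the identity.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, as.numeric(-rt %*% t$translation))
}

#' Homogeneous 4x4 matrix form of a rigid transform
#' @param t a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
rt_to_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' @rdname rt_to_matrix
#' @param m 4x4 homogeneous matrix with a rigid upper-left block.
#' @export
rt_from_matrix <- function(m) rigid_transform(m[1:3, 1:3], m[1:3, 4])

# largest translation/rotation deviation between two transforms, used for
# pose deduplication and tests
rt_distance <- function(a, b) {
  dt <- max(abs(a$translation - b$translation))
  dr <- max(abs(a$rotation - b$rotation))
  c(translation_mm = dt, rotation = dr)
}
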