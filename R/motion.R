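MOTION_PATTERNS <- c("linear", "circular", "linear_plus_circular",
                     "brownian", "spiral", "random_back_forth")

#' The six supported motion pattern names
#' @return Character vector of pattern names accepted by [generate_motion()].
#' @export
motion_patterns <- function() MOTION_PATTERNS

#' Generate a rigid motion track
#'
#' Produces a timestamped sequence of rigid transforms at a fixed tracker
#' frame rate, following one of six parameterised in-plane motion patterns.
#' The first frame is always the identity (reference pose) and the per-frame
#' displacement magnitude is governed by `amplitude_step`:
#'
#' * `linear`: constant-direction translation steps of length `amplitude_step`
#'   along `direction_deg`, ping-ponging at `bound`.
#' * `circular`: rotation about the isocenter with constant angular step such
#'   that the arc length at `arc_radius` (the phantom's outermost active
#'   radius) equals `amplitude_step`.
#' * `linear_plus_circular`: sum of the two above.
#' * `brownian`: seeded isotropic Gaussian translation steps with RMS step
#'   norm `amplitude_step` (unbounded; desk-scale tracks are short).
#' * `spiral`: translation along an Archimedean spiral with constant arc-length
#'   steps of `amplitude_step` and radial pitch `spiral_pitch` per turn.
#' * `random_back_forth`: seeded out-and-back strokes — a run of fixed-length
#'   steps along a random direction is retraced back to its start before a new
#'   direction is drawn; stroke excursions stay within `bound`.
#'
#' `amplitude_step = 0` yields identity transforms for every pattern.
#'
#' @param pattern one of `r paste(MOTION_PATTERNS, collapse = ", ")`.
#' @param amplitude_step per-frame displacement magnitude (mm).
#' @param n_frames number of tracker frames (>= 1).
#' @param frame_rate tracker frame rate (Hz), one of 20, 30, 60.
#' @param seed RNG seed (used by brownian and random_back_forth only).
#' @param bound translation bound (mm) for linear and random_back_forth.
#' @param direction_deg linear motion direction (degrees from +x).
#' @param arc_radius radius (mm) at which the circular arc step equals
#'   `amplitude_step`.
#' @param spiral_pitch radial growth per turn of the spiral (mm).
#' @return A tibble of class `petsr_track` with columns `frame`, `time_ms`,
#'   `tx, ty, tz` (mm) and `rx, ry, rz` (degrees, Z.Y.X intrinsic). The pose of
#'   frame k holds from `time_ms[k]` until the next frame.
#' @examples
#' tr <- generate_motion("linear", amplitude_step = 1, n_frames = 10)
#' tr
#' @export
generate_motion <- function(pattern, amplitude_step, n_frames = 100,
                            frame_rate = 60, seed = 1L, bound = 6,
                            direction_deg = 30, arc_radius = 18,
                            spiral_pitch = 2) {
  pattern <- match.arg(pattern, MOTION_PATTERNS)
  stopifnot(amplitude_step >= 0, n_frames >= 1)
  if (!frame_rate %in% c(20, 30, 60)) stop("frame_rate must be 20, 30 or 60 Hz")
  n <- as.integer(n_frames)
  step <- amplitude_step
  txy <- matrix(0, n, 2)
  rz <- numeric(n)

  ping_pong <- function(n, step, bound) {
    s <- numeric(n); ds <- step
    for (k in seq_len(n)[-1]) {
      val <- s[k - 1] + ds
      if (val > bound) { val <- 2 * bound - val; ds <- -ds }
      if (val < -bound) { val <- -2 * bound - val; ds <- -ds }
      s[k] <- val
    }
    s
  }

  if (step > 0) {
    if (pattern %in% c("linear", "linear_plus_circular")) {
      th <- direction_deg * pi / 180
      s <- ping_pong(n, step, bound)
      txy <- cbind(s * cos(th), s * sin(th))
    }
    if (pattern %in% c("circular", "linear_plus_circular")) {
      dtheta <- step / arc_radius * 180 / pi
      rz <- (seq_len(n) - 1) * dtheta
    }
    if (pattern == "brownian") {
      txy <- withr::with_seed(seed, {
        steps <- matrix(stats::rnorm(2 * (n - 1), sd = step / sqrt(2)), n - 1, 2)
        rbind(c(0, 0), apply(steps, 2, cumsum))
      })
    }
    if (pattern == "spiral") {
      c0 <- spiral_pitch / (2 * pi)
      phi <- 0
      for (k in seq_len(n)[-1]) {
        rho <- c0 * phi
        phi <- phi + step / sqrt(rho^2 + c0^2)
        txy[k, ] <- c0 * phi * c(cos(phi), sin(phi))
      }
      txy <- sweep(txy, 2, txy[1, ])
    }
    if (pattern == "random_back_forth") {
      # out-and-back strokes: walk `len` fixed steps along a random direction,
      # retrace them to the start, draw a new direction; positions are
      # revisited, which is what distinguishes back-and-forth motion from a
      # free random walk
      max_run <- max(1L, min(4L, floor(bound / step)))
      txy <- withr::with_seed(seed, {
        p <- matrix(0, n, 2)
        pos <- c(0, 0)
        k <- 2L
        while (k <= n) {
          th <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(th), sin(th))
          len <- sample.int(max_run, 1)
          for (sgn in c(1, -1)) {
            for (j in seq_len(len)) {
              if (k > n) break
              pos <- pos + sgn * step * dir
              p[k, ] <- pos
              k <- k + 1L
            }
          }
        }
        p
      })
    }
  }

  out <- tibble::tibble(frame = seq_len(n),
                        time_ms = (seq_len(n) - 1) * 1000 / frame_rate,
                        tx = txy[, 1], ty = txy[, 2], tz = 0,
                        rx = 0, ry = 0, rz = rz)
  structure(out, class = c("petsr_track", class(out)),
            pattern = pattern, amplitude_step = amplitude_step,
            frame_rate = frame_rate)
}

#' Build a motion track from explicit transforms
#'
#' @param time_ms frame timestamps (ms, strictly increasing).
#' @param transforms list of `rigid_transform`, one per frame.
#' @return A `petsr_track` tibble.
#' @export
motion_track <- function(time_ms, transforms) {
  stopifnot(length(time_ms) == length(transforms))
  if (any(diff(time_ms) <= 0)) stop("frame times must be strictly increasing")
  eul <- dplyr::bind_rows(lapply(transforms, rt_to_euler))
  out <- tibble::tibble(frame = seq_along(time_ms), time_ms = as.numeric(time_ms),
                        tx = eul$tx, ty = eul$ty, tz = eul$tz,
                        rx = eul$rx, ry = eul$ry, rz = eul$rz)
  structure(out, class = c("petsr_track", class(out)))
}

#' Identity (static) track
#' @inheritParams generate_motion
#' @return A `petsr_track` of identity poses.
#' @export
static_track <- function(n_frames = 1, frame_rate = 60) {
  generate_motion("linear", amplitude_step = 0, n_frames = n_frames,
                  frame_rate = frame_rate)
}

#' Rigid transforms of a motion track
#' @param track a `petsr_track`.
#' @return List of `rigid_transform`, one per frame.
#' @export
track_transforms <- function(track) {
  purrr::pmap(list(track$tx, track$ty, track$tz, track$rx, track$ry, track$rz),
              rt_from_euler)
}

# Deduplicate consecutive-equal poses: frames whose transform parameters agree
# within tol_mm / tol_deg share a pose id. Returns list(pose_of_frame,
# transforms (unique), weight (frame share per pose)).
dedupe_poses <- function(track, tol_mm = 0.01, tol_deg = 0.01) {
  key <- paste(round(track$tx / tol_mm), round(track$ty / tol_mm),
               round(track$tz / tol_mm), round(track$rx / tol_deg),
               round(track$ry / tol_deg), round(track$rz / tol_deg))
  uid <- match(key, unique(key))
  first <- match(seq_len(max(uid)), uid)
  tr <- track_transforms(track[first, ])
  w <- as.numeric(tabulate(uid, max(uid))) / length(uid)
  list(pose_of_frame = uid, transforms = tr, weight = w)
}

#' Plot the translation path of a motion track
#' @param object a `petsr_track`.
#' @param ... unused.
#' @return A ggplot object showing the in-plane path of a tracked point.
#' @method autoplot petsr_track
#' @export
autoplot.petsr_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tx, y = .data$ty,
                                       colour = .data$time_ms)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tx (mm)", y = "ty (mm)", colour = "time (ms)")
}
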