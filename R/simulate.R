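#' Per-pose expected counts for a moving acquisition
#'
#' Computes the forward-model expectation used by the list-mode simulator:
#' for each deduplicated pose of the track, the PSF-augmented multi-ray
#' forward projection of the static phantom along the inverse-transformed
#' LORs, optionally thinned by the attenuation of the co-moving attenuation
#' map. Useful as an exact oracle for distributional tests and for noise-free
#' reconstruction studies.
#'
#' @param phantom a `phantom`.
#' @param track a `petsr_track` covering the acquisition.
#' @param g a `scanner_geometry`.
#' @param psf a `psf_model`.
#' @param cfg a `projector_config` (its `crystal_width` defaults to the
#'   geometry's).
#' @param total_counts if not NULL, expectations are scaled so their grand
#'   total (over all frames) equals this.
#' @return A list with `rate` (n_lor x n_pose matrix of expected counts per ms
#'   at unit scale, already scaled if `total_counts` given), `lors`,
#'   `pose_of_frame`, `frame_dur_ms`, and `expected` (n_lor x n_frames matrix
#'   of per-frame expected counts).
#' @export
listmode_expectation <- function(phantom, track, g, psf = psf_model(),
                                 cfg = NULL, total_counts = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(g, "scanner_geometry"))
  if (is.null(cfg)) cfg <- projector_config(crystal_width = g$crystal_width)
  lors <- enumerate_lors(g)
  poses <- dedupe_poses(track, tol_mm = 1e-6, tol_deg = 1e-6)
  imgb <- smooth_image(phantom$activity, psf$image_fwhm)
  offs <- ray_offsets(cfg$crystal_width, psf$proj_fwhm, cfg$n_rays)
  gd <- imgb$grid
  ends <- cbind(lors$ax, lors$ay, 0)
  ends2 <- cbind(lors$bx, lors$by, 0)
  n_lor <- nrow(lors)

  proj_pose <- function(tr) {
    ti <- invert(tr)
    a <- apply_rigid(ti, ends); b <- apply_rigid(ti, ends2)
    r <- expand_rays(a[, 1], a[, 2], b[, 1], b[, 2], offs)
    fwd <- cpp_siddon_forward(imgb$values, gd$origin[1], gd$origin[2],
                              gd$voxel_size[1], gd$voxel_size[2],
                              r$p1x, r$p1y, r$p2x, r$p2y, r$bin, r$w, n_lor)
    if (!is.null(phantom$attenuation)) {
      mu <- phantom$attenuation
      gm <- mu$grid
      att <- cpp_siddon_forward(mu$values, gm$origin[1], gm$origin[2],
                                gm$voxel_size[1], gm$voxel_size[2],
                                r$p1x, r$p1y, r$p2x, r$p2y, r$bin, r$w, n_lor)
      fwd <- fwd * exp(-att)
    }
    fwd
  }
  rate <- vapply(poses$transforms, proj_pose, numeric(n_lor))
  rate <- matrix(rate, nrow = n_lor)

  nfr <- nrow(track)
  dur <- diff(track$time_ms)
  frame_dur <- c(dur, if (nfr > 1) stats::median(dur) else 1000)
  expected <- rate[, poses$pose_of_frame, drop = FALSE] *
    matrix(frame_dur, n_lor, nfr, byrow = TRUE)
  if (!is.null(total_counts)) {
    tot <- sum(expected)
    if (tot <= 0) {
      scl <- 0
    } else {
      scl <- total_counts / tot
    }
    expected <- expected * scl
    rate <- rate * scl
  }
  list(rate = rate, lors = lors, pose_of_frame = poses$pose_of_frame,
       frame_dur_ms = frame_dur, expected = expected)
}

#' Simulate a list-mode acquisition under continuous rigid motion
#'
#' Emission events are generated frame by frame: the expected number of
#' coincidences on each LOR is proportional to the forward projection of the
#' phantom moved to the frame's pose (equivalently, of the static phantom
#' along the inversely transformed LOR), times the frame duration, globally
#' scaled so the total expectation equals `total_counts`. Per-LOR counts are
#' Poisson with the stated seed and event timestamps are uniform within their
#' frame. An optional uniform randoms contribution exercises the additive
#' terms of the reconstruction model.
#'
#' @inheritParams listmode_expectation
#' @param total_counts expected total number of events (> 0).
#' @param seed integer seed controlling all randomness; identical seeds give
#'   byte-identical event streams.
#' @param randoms_fraction fraction of `total_counts` added as spatially and
#'   temporally uniform random coincidences (default 0).
#' @param pulse_stride a synchronisation pulse is emitted at every
#'   `pulse_stride`-th frame time.
#' @return A tibble of class `petsr_listmode` with columns `timestamp_ms`,
#'   `det_a`, `det_b`, `lor` (index into [enumerate_lors()] ordering), sorted
#'   by timestamp, with attributes `geometry`, `duration_ms`, `pulse_train`
#'   and `seed`.
#' @export
simulate_listmode <- function(phantom, track, g, psf = psf_model(),
                              cfg = NULL, total_counts, seed,
                              randoms_fraction = 0, pulse_stride = 60) {
  stopifnot(total_counts > 0)
  if (is.null(cfg)) cfg <- projector_config(crystal_width = g$crystal_width)
  ex <- listmode_expectation(phantom, track, g, psf, cfg,
                             total_counts = total_counts * (1 - randoms_fraction))
  lam <- ex$expected
  n_lor <- nrow(ex$lors)
  nfr <- ncol(lam)
  if (randoms_fraction > 0) {
    lam <- lam + randoms_fraction * total_counts / (n_lor * nfr)
  }
  t0 <- track$time_ms
  dur <- ex$frame_dur_ms

  ev <- withr::with_seed(as.integer(seed), {
    counts <- matrix(stats::rpois(length(lam), lam), nrow = n_lor)
    ne <- sum(counts)
    lor_id <- integer(ne); ts <- numeric(ne)
    pos <- 0L
    for (f in seq_len(nfr)) {
      cf <- counts[, f]
      nf <- sum(cf)
      if (nf == 0L) next
      idx <- pos + seq_len(nf)
      lor_id[idx] <- rep.int(seq_len(n_lor), cf)
      ts[idx] <- stats::runif(nf, t0[f], t0[f] + dur[f])
      pos <- pos + nf
    }
    tibble::tibble(timestamp_ms = ts, lor = lor_id)
  })
  ev <- dplyr::arrange(ev, .data$timestamp_ms)
  ev <- dplyr::mutate(ev,
                      det_a = ex$lors$det_a[.data$lor],
                      det_b = ex$lors$det_b[.data$lor],
                      .before = "lor")
  dur_total <- max(track$time_ms) + dur[length(dur)]
  pulses <- track$time_ms[seq(1L, nrow(track), by = pulse_stride)]
  out <- structure(ev, class = c("petsr_listmode", class(ev)),
                   geometry = g, duration_ms = dur_total,
                   pulse_train = pulse_train(pulses), seed = as.integer(seed))
  out
}

#' Noise-free pseudo list-mode data
#'
#' Builds a weighted event stream whose per-(LOR, frame) weights equal the
#' exact forward-model expectations, i.e. the infinite-count limit of
#' [simulate_listmode()]. The reconstruction treats the `weight` column as
#' fractional event counts, which makes deterministic convergence studies
#' possible at desk scale.
#'
#' @inheritParams simulate_listmode
#' @return A `petsr_listmode` tibble with an extra `weight` column; one row per
#'   (LOR, frame) with positive expectation, timestamped at the frame midpoint.
#' @export
expected_listmode <- function(phantom, track, g, psf = psf_model(),
                              cfg = NULL, total_counts = 1e6) {
  if (is.null(cfg)) cfg <- projector_config(crystal_width = g$crystal_width)
  ex <- listmode_expectation(phantom, track, g, psf, cfg, total_counts = total_counts)
  lam <- ex$expected
  nfr <- ncol(lam)
  n_lor <- nrow(ex$lors)
  keep <- which(lam > 0)
  lor_id <- ((keep - 1L) %% n_lor) + 1L
  f <- ((keep - 1L) %/% n_lor) + 1L
  ev <- tibble::tibble(timestamp_ms = track$time_ms[f] + ex$frame_dur_ms[f] / 2,
                       det_a = ex$lors$det_a[lor_id],
                       det_b = ex$lors$det_b[lor_id],
                       lor = lor_id,
                       weight = lam[keep])
  ev <- dplyr::arrange(ev, .data$timestamp_ms, .data$lor)
  dur_total <- max(track$time_ms) + ex$frame_dur_ms[nfr]
  structure(ev, class = c("petsr_listmode", class(ev)),
            geometry = g, duration_ms = dur_total,
            pulse_train = pulse_train(track$time_ms[1]), seed = NA_integer_)
}

#' @export
print.petsr_listmode <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<petsr_listmode> %d events over %.1f ms, %d detectors\n",
              nrow(x), attr(x, "duration_ms"), g$n_detectors))
  NextMethod()
}
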