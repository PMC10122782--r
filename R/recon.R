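#' Reconstruction configuration
#'
#' @param grid target `voxel_grid` (e.g. 2 mm pitch for a standard
#'   reconstruction, 0.8-1 mm for super-resolution).
#' @param n_iterations number of full OSEM iterations (>= 1).
#' @param n_subsets number of ordered subsets; events are interleaved
#'   round-robin by arrival order so every subset spans all poses.
#' @param psf a `psf_model`.
#' @param projector a `projector_config`; a zero `crystal_width` is replaced by
#'   the scanner geometry's at reconstruction time.
#' @param sensitivity_method `"image_space_average"` (one back-projection, then
#'   pose-resampled averaging in image space) or `"projection_space_per_pose"`
#'   (per-pose LOR transformation and back-projection, the reference method).
#' @param sensitivity_floor voxels whose time-averaged sensitivity falls below
#'   this fraction of the maximum are masked out of the update and frozen at 0.
#' @param seed reserved for subset shuffling; the default round-robin subset
#'   formation is deterministic.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(grid, n_iterations = 6, n_subsets = 4,
                         psf = psf_model(), projector = projector_config(),
                         sensitivity_method = c("image_space_average",
                                                "projection_space_per_pose"),
                         sensitivity_floor = 1e-3, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"), n_iterations >= 1, n_subsets >= 1,
            sensitivity_floor >= 0, sensitivity_floor < 1)
  structure(list(grid = grid, n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), psf = psf,
                 projector = projector,
                 sensitivity_method = match.arg(sensitivity_method),
                 sensitivity_floor = sensitivity_floor, seed = as.integer(seed)),
            class = "recon_config")
}

#' Correction factors for the reconstruction model
#'
#' Multiplicative and additive data-correction terms. `norm` (detector
#' sensitivity N) and `static_attenuation` (H, non-moving components such as
#' the bed) are per-LOR factors in (0, 1]; `scatter` and `randoms` are
#' per-event expected additive counts; `combined_attenuation` (a) is the
#' attenuation on the uncorrected LOR. The moving-object attenuation I is
#' derived from an attenuation map at reconstruction time. Defaults are unit /
#' zero corrections.
#'
#' @param norm,static_attenuation,combined_attenuation scalars or per-LOR
#'   vectors in (0, 1].
#' @param scatter,randoms scalar expected additive counts per event (>= 0).
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(norm = 1, static_attenuation = 1,
                               combined_attenuation = 1,
                               scatter = 0, randoms = 0) {
  stopifnot(all(norm > 0), all(norm <= 1), all(static_attenuation > 0),
            all(static_attenuation <= 1), all(combined_attenuation > 0),
            all(combined_attenuation <= 1), scatter >= 0, randoms >= 0)
  structure(list(norm = norm, static_attenuation = static_attenuation,
                 combined_attenuation = combined_attenuation,
                 scatter = scatter, randoms = randoms),
            class = "correction_factors")
}

#' Assign list-mode events to tracker frames
#'
#' Each event is mapped to the frame whose time interval contains its
#' timestamp (pose held from a frame's timestamp until the next frame; the
#' last frame holds until the end of the acquisition). An event exactly at a
#' frame timestamp belongs to that frame. The optional clock synchronisation
#' maps tracker frame times onto the event clock before assignment.
#'
#' @param lm a `petsr_listmode` tibble (or any tibble with `timestamp_ms`).
#' @param track a `petsr_track`.
#' @param sync optional result of [align_timebases()].
#' @param policy what to do with events before the tracked span: `"drop"`
#'   (returned as frame 0) or `"error"`.
#' @return Integer frame index per event (0 = outside tracked span when
#'   `policy = "drop"`).
#' @export
assign_frames <- function(lm, track, sync = NULL, policy = c("drop", "error")) {
  policy <- match.arg(policy)
  ft <- apply_timebase(track$time_ms, sync)
  idx <- findInterval(lm$timestamp_ms, ft)
  if (any(idx == 0L)) {
    if (policy == "error") stop("events before the tracked span")
  }
  as.integer(idx)
}

#' Motion-correct LOR endpoints
#'
#' Transforms both endpoints of each LOR by the inverse of the frame's motion
#' transform, mapping the measured chord back to the reference frame. The
#' result is a free chord (endpoints no longer on crystals) and is projected
#' as such.
#'
#' @param lors tibble with endpoint columns `ax, ay, bx, by` (mm, z = 0).
#' @param transform the frame's motion `rigid_transform` (reference -> frame).
#' @return The LOR tibble with transformed endpoints. Out-of-plane components
#'   produced by 3D transforms are dropped by the 2D projector.
#' @export
motion_correct_lor <- function(lors, transform) {
  ti <- invert(transform)
  a <- apply_rigid(ti, cbind(lors$ax, lors$ay, 0))
  b <- apply_rigid(ti, cbind(lors$bx, lors$by, 0))
  dplyr::mutate(lors, ax = a[, 1], ay = a[, 2], bx = b[, 1], by = b[, 2])
}

#' Time-averaged sensitivity image
#'
#' The EM denominator for a moving acquisition: the back-projection of the
#' per-LOR factors N*H, averaged over the poses of the track. Two strategies
#' are provided. `image_space_average` back-projects once and averages the
#' image resampled at each pose (fast; bilinear inverse mapping).
#' `projection_space_per_pose` transforms every LOR per pose and
#' back-projects each time (the reference method, exact up to the projector).
#' Consecutive frames whose transform differs by less than 0.01 mm / 0.01
#' degrees are merged before averaging.
#'
#' @param track a `petsr_track` (NULL for a static acquisition).
#' @param g a `scanner_geometry`.
#' @param cfg a `recon_config`.
#' @param corrections a `correction_factors`.
#' @return A `pet_image` of per-voxel sensitivities (>= 0).
#' @export
compute_sensitivity <- function(track, g, cfg,
                                corrections = correction_factors()) {
  stopifnot(inherits(cfg, "recon_config"), inherits(g, "scanner_geometry"))
  proj <- cfg$projector
  if (proj$crystal_width == 0) proj$crystal_width <- g$crystal_width
  lors <- enumerate_lors(g)
  nh <- rep_len(corrections$norm * corrections$static_attenuation, nrow(lors))
  if (is.null(track)) track <- static_track()
  if (nrow(track) == 0) stop("empty motion track")
  poses <- dedupe_poses(track)

  all_identity <- all(vapply(poses$transforms, function(tr) {
    max(rt_distance(tr, rt_identity())) < 1e-12
  }, logical(1)))

  if (all_identity) {
    # static acquisition: both strategies reduce to the plain back-projection
    acc <- back_project(nh, lors, cfg$grid, cfg$psf, proj)$values
  } else if (cfg$sensitivity_method == "image_space_average") {
    co <- as.matrix(grid_coordinates(cfg$grid)[, c("x", "y")])
    co3 <- cbind(co, 0)
    # pad the static back-projection so pose-resampled points stay on-grid
    pad_mm <- 0
    for (tr in poses$transforms) {
      corners <- co3[c(1, cfg$grid$dims[1],
                       length(co3[, 1]) - cfg$grid$dims[1] + 1,
                       length(co3[, 1])), , drop = FALSE]
      pad_mm <- max(pad_mm, abs(apply_rigid(tr, corners) - corners))
    }
    padv <- ceiling(pad_mm / cfg$grid$voxel_size) + 1L
    pgrid <- voxel_grid(cfg$grid$dims + 2L * padv, cfg$grid$voxel_size,
                        cfg$grid$origin - padv * cfg$grid$voxel_size)
    s0 <- back_project(nh, lors, pgrid, cfg$psf, proj)
    acc <- matrix(0, cfg$grid$dims[1], cfg$grid$dims[2])
    for (u in seq_along(poses$transforms)) {
      tr <- poses$transforms[[u]]
      pts <- apply_rigid(tr, co3)[, 1:2, drop = FALSE]
      acc <- acc + poses$weight[u] *
        matrix(interp_bilinear(s0, pts), cfg$grid$dims[1], cfg$grid$dims[2])
    }
  } else {
    acc <- matrix(0, cfg$grid$dims[1], cfg$grid$dims[2])
    for (u in seq_along(poses$transforms)) {
      tl <- motion_correct_lor(lors, poses$transforms[[u]])
      acc <- acc + poses$weight[u] *
        back_project(nh, tl, cfg$grid, cfg$psf, proj)$values
    }
  }
  pet_image(cfg$grid, pmax(acc, 0))
}

#' Event-by-event motion-compensated list-mode OSEM reconstruction
#'
#' Implements the super-resolution update: for each event in the current
#' subset, the current estimate (blurred by the image-space PSF kernel) is
#' forward-projected along the motion-corrected LOR with the multi-ray
#' projector, scaled by the moving attenuation factor and offset by the
#' additive scatter/randoms term normalised by the combined attenuation and
#' detector sensitivity; the resulting count ratio is back-projected (adjoint
#' path, including the image-space kernel) and the estimate is multiplied
#' voxel-wise by the ratio image over the time-averaged sensitivity. Voxels
#' below the sensitivity floor are frozen at zero. Events sharing a LOR and a
#' (deduplicated) pose contribute identical system-matrix rows and are
#' aggregated, which leaves the update exactly unchanged while keeping the
#' per-iteration cost bounded by the number of distinct (LOR, pose) pairs.
#'
#' With one subset and no additive terms the update is maximum-likelihood EM,
#' whose Poisson log-likelihood is non-decreasing across iterations.
#'
#' @param lm a `petsr_listmode` tibble; an optional `weight` column is treated
#'   as fractional event counts (see [expected_listmode()]).
#' @param track a `petsr_track` covering the acquisition.
#' @param cfg a `recon_config`.
#' @param corrections a `correction_factors`.
#' @param motion_correction set FALSE to reconstruct ignoring the track
#'   (events treated as acquired at the reference pose).
#' @param sync optional clock alignment from [align_timebases()].
#' @param attenuation optional co-moving attenuation map (`pet_image`, mm^-1)
#'   line-integrated along each transformed LOR to form the per-event moving
#'   attenuation factor I.
#' @param event_policy policy for events outside the tracked span
#'   (see [assign_frames()]).
#' @param background_roi optional logical mask (grid-shaped) whose standard
#'   deviation is recorded per iteration, to match image noise levels across
#'   methods.
#' @return An object of class `petsr_recon`: list with `image` (`pet_image`),
#'   `trace` (tibble: iteration, loglik, bg_sd), `sensitivity`, `mask`,
#'   `config` and bookkeeping counts. The log-likelihood trace includes the
#'   additive terms and is exact for `n_subsets = 1` (diagnostic for more
#'   subsets).
#' @export
lm_osem_sr <- function(lm, track, cfg, corrections = correction_factors(),
                       motion_correction = TRUE, sync = NULL,
                       attenuation = NULL, event_policy = "drop",
                       background_roi = NULL) {
  stopifnot(inherits(cfg, "recon_config"))
  g <- attr(lm, "geometry")
  if (is.null(g)) stop("list-mode data lacks a geometry attribute")
  proj <- cfg$projector
  if (proj$crystal_width == 0) proj$crystal_width <- g$crystal_width
  lors <- enumerate_lors(g)
  n_lor <- nrow(lors)

  frame <- assign_frames(lm, track, sync, policy = event_policy)
  keep <- frame >= 1L & frame <= nrow(track)
  n_dropped <- sum(!keep)
  ev_lor <- lm$lor[keep]
  ev_frame <- frame[keep]
  w <- if ("weight" %in% names(lm)) lm$weight[keep] else rep(1, sum(keep))

  # empty data is a fixed point: one update of a uniform start gives zero
  if (length(ev_lor) == 0L) {
    sens <- compute_sensitivity(if (motion_correction) track else NULL, g, cfg,
                                corrections)
    mask <- sens$values >= cfg$sensitivity_floor * max(sens$values)
    return(structure(list(image = pet_image(cfg$grid, 0),
                          trace = tibble::tibble(iteration = integer(),
                                                 loglik = numeric(),
                                                 bg_sd = numeric()),
                          sensitivity = sens, mask = mask, config = cfg,
                          n_events = 0, n_dropped = n_dropped, n_poses = 0L,
                          n_frames = nrow(track),
                          motion_correction = motion_correction),
                     class = "petsr_recon"))
  }
  if (cfg$n_subsets > length(ev_lor)) stop("empty subset: more subsets than events")

  if (motion_correction) {
    poses <- dedupe_poses(track)
    pose_id <- poses$pose_of_frame[ev_frame]
    transforms <- poses$transforms
    sens_track <- track
  } else {
    pose_id <- rep(1L, length(ev_lor))
    transforms <- list(rt_identity())
    sens_track <- NULL
  }

  n_subsets <- cfg$n_subsets
  subset <- ((seq_along(ev_lor) - 1L) %% n_subsets) + 1L

  # aggregate events by (subset, LOR, pose): identical system-matrix rows
  key <- (pose_id - 1L) * n_lor + ev_lor
  ukey <- sort(unique(key))
  combo_of_event <- match(key, ukey)
  n_combo <- length(ukey)
  combo_lor <- ((ukey - 1L) %% n_lor) + 1L
  combo_pose <- ((ukey - 1L) %/% n_lor) + 1L

  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(subset = subset, combo = combo_of_event, w = w),
                    .data$subset, .data$combo),
    w = sum(.data$w), .groups = "drop")

  # motion-corrected endpoints per combo
  aXY <- matrix(0, n_combo, 2); bXY <- matrix(0, n_combo, 2)
  for (p in unique(combo_pose)) {
    sel <- combo_pose == p
    tl <- motion_correct_lor(lors[combo_lor[sel], ], transforms[[p]])
    aXY[sel, ] <- cbind(tl$ax, tl$ay)
    bXY[sel, ] <- cbind(tl$bx, tl$by)
  }

  offs <- ray_offsets(proj$crystal_width, cfg$psf$proj_fwhm, proj$n_rays)
  k <- length(offs)
  rays <- expand_rays(aXY[, 1], aXY[, 2], bXY[, 1], bXY[, 2], offs)
  ord <- order(rays$bin)            # combo-major ray blocks
  rp1x <- rays$p1x[ord]; rp1y <- rays$p1y[ord]
  rp2x <- rays$p2x[ord]; rp2y <- rays$p2y[ord]

  # moving attenuation per combo (I) and additive term (S+R)/(a*N)
  if (!is.null(attenuation)) {
    ga <- attenuation$grid
    mu <- cpp_siddon_forward(attenuation$values, ga$origin[1], ga$origin[2],
                             ga$voxel_size[1], ga$voxel_size[2],
                             rp1x, rp1y, rp2x, rp2y,
                             rep(seq_len(n_combo) - 1L, each = k),
                             rep(1 / k, n_combo * k), n_combo)
    att_i <- exp(-mu)
  } else {
    att_i <- rep(1, n_combo)
  }
  nvec <- rep_len(corrections$norm, n_lor)
  avec <- rep_len(corrections$combined_attenuation, n_lor)
  additive <- (corrections$scatter + corrections$randoms) /
    (avec[combo_lor] * nvec[combo_lor])

  # per-subset views with ray endpoints materialised once
  sub_rows <- split(seq_len(nrow(agg)), agg$subset)
  sub <- lapply(sub_rows, function(rows) {
    combos <- agg$combo[rows]
    ray <- rep((combos - 1L) * k, each = k) + rep(seq_len(k), length(combos))
    list(w = agg$w[rows],
         add = additive[combos],
         att = att_i[combos],
         n = length(combos),
         p1x = rp1x[ray], p1y = rp1y[ray], p2x = rp2x[ray], p2y = rp2y[ray],
         bin = rep(seq_along(combos) - 1L, each = k),
         wray = rep(1 / k, length(combos) * k))
  })

  sens <- compute_sensitivity(sens_track, g, cfg, corrections)
  smax <- max(sens$values)
  if (smax <= 0) stop("sensitivity image is identically zero")
  mask <- sens$values >= cfg$sensitivity_floor * smax
  s_sub <- sens$values / n_subsets

  gd <- cfg$grid
  est <- matrix(0, gd$dims[1], gd$dims[2])
  est[mask] <- 1
  trace <- vector("list", cfg$n_iterations)

  for (it in seq_len(cfg$n_iterations)) {
    ll <- 0
    for (s in seq_along(sub)) {
      ss <- sub[[s]]
      imgb <- smooth_image(pet_image(gd, est, nonneg = FALSE), cfg$psf$image_fwhm)
      fwd <- cpp_siddon_forward(imgb$values, gd$origin[1], gd$origin[2],
                                gd$voxel_size[1], gd$voxel_size[2],
                                ss$p1x, ss$p1y, ss$p2x, ss$p2y,
                                ss$bin, ss$wray, ss$n)
      lam <- ss$att * fwd + ss$add
      ll <- ll + sum(ss$w * log(pmax(lam, 1e-300))) -
        sum(s_sub * est)
      ratio <- ifelse(lam > 0, ss$w * ss$att / lam, 0)
      bp <- cpp_siddon_back(ratio, gd$dims[1], gd$dims[2],
                            gd$origin[1], gd$origin[2],
                            gd$voxel_size[1], gd$voxel_size[2],
                            ss$p1x, ss$p1y, ss$p2x, ss$p2y, ss$bin, ss$wray)
      bp <- smooth_image(pet_image(gd, bp, nonneg = FALSE), cfg$psf$image_fwhm)$values
      upd <- est * bp
      upd[mask] <- upd[mask] / s_sub[mask]
      upd[!mask] <- 0
      est <- upd
    }
    trace[[it]] <- tibble::tibble(
      iteration = it, loglik = ll,
      bg_sd = if (is.null(background_roi)) NA_real_ else stats::sd(est[background_roi]))
  }

  structure(list(image = pet_image(gd, est),
                 trace = dplyr::bind_rows(trace),
                 sensitivity = sens, mask = mask, config = cfg,
                 n_events = sum(w), n_dropped = n_dropped,
                 n_poses = length(transforms),
                 n_frames = nrow(track),
                 motion_correction = motion_correction),
            class = "petsr_recon")
}

#' @export
print.petsr_recon <- function(x, ...) {
  cat(sprintf("<petsr_recon> %d x %d @ %g mm; %d iterations x %d subsets; %s events, %d poses\n",
              x$config$grid$dims[1], x$config$grid$dims[2],
              x$config$grid$voxel_size[1], x$config$n_iterations,
              x$config$n_subsets, format(x$n_events), x$n_poses))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration reconstruction trace
#' @param x a `petsr_recon`.
#' @param ... unused.
#' @return Tibble with `iteration`, `loglik` and `bg_sd`.
#' @method tidy petsr_recon
#' @export
tidy.petsr_recon <- function(x, ...) x$trace

#' One-row reconstruction summary
#' @param x a `petsr_recon`.
#' @param ... unused.
#' @return Tibble with iteration counts, event counts, pose counts, the final
#'   log-likelihood and the total forward-projected expectation
#'   `sum(sensitivity * image)` (which converges to the event count for
#'   maximum-likelihood EM with unit corrections).
#' @method glance petsr_recon
#' @export
glance.petsr_recon <- function(x, ...) {
  tibble::tibble(n_iterations = x$config$n_iterations,
                 n_subsets = x$config$n_subsets,
                 n_events = x$n_events, n_dropped = x$n_dropped,
                 n_poses = x$n_poses, n_frames = x$n_frames,
                 motion_correction = x$motion_correction,
                 loglik = x$trace$loglik[nrow(x$trace)],
                 total_expected = sum(x$sensitivity$values * x$image$values))
}

#' @method autoplot petsr_recon
#' @export
autoplot.petsr_recon <- function(object, ...) {
  autoplot(object$image) + ggplot2::labs(fill = "activity")
}

#' @export
plot.petsr_recon <- function(x, ...) print(autoplot(x, ...))
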