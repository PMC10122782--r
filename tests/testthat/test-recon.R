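test_that("assign_frames uses half-open frame intervals on the event clock", {
  tr <- static_track(10, frame_rate = 60)   # frames at 0, 16.67, 33.33, ... ms
  lm <- tibble::tibble(timestamp_ms = c(0, 16.6666667, 20, 33.3, 149, -5))
  f <- assign_frames(lm, tr)
  expect_equal(f[1], 1L)            # exactly at a frame timestamp
  expect_equal(f[2], 2L)
  expect_equal(f[3], 2L)            # 20 ms lies in [16.67, 33.33)
  expect_equal(f[4], 2L)
  expect_equal(f[5], 9L)
  expect_equal(f[6], 0L)            # before the track: dropped
  expect_error(assign_frames(lm, tr, policy = "error"), "before the tracked span")

  # a clock offset undone before assignment reproduces the shifted result
  sync <- list(offset_ms = 123.4, drift_ppm = 0)
  f2 <- assign_frames(tibble::tibble(timestamp_ms = lm$timestamp_ms + 123.4),
                      tr, sync = sync)
  expect_equal(f2, f)
})

test_that("motion_correct_lor transforms endpoints by the inverse motion", {
  lors <- tibble::tibble(ax = c(-50, 0), ay = c(0, 40), bx = c(50, 0),
                         by = c(0, -40))
  expect_equal(motion_correct_lor(lors, rt_identity()), lors)

  d <- c(2, -3)
  mc <- motion_correct_lor(lors, rt_translation(c(d, 0)))
  expect_equal(mc$ax, lors$ax - d[1])
  expect_equal(mc$by, lors$by - d[2])

  withr::with_seed(41, {
    # in-plane motion (the projector's plane): round trip is exact
    t <- compose(rt_rotation_z(stats::runif(1, -20, 20)),
                 rt_translation(c(stats::runif(2, -10, 10), 0)))
    round <- motion_correct_lor(motion_correct_lor(lors, invert(t)), t)
    expect_equal(as.data.frame(round), as.data.frame(lors), tolerance = 1e-9)
  })
})

test_that("both sensitivity strategies equal plain back-projection when static", {
  s <- tiny_setup(16)
  grid <- voxel_grid(24, 2)
  tr <- static_track(5)
  base <- back_project(rep(1, nrow(enumerate_lors(s$g))), enumerate_lors(s$g),
                       grid, s$psf, s$proj)
  for (m in c("image_space_average", "projection_space_per_pose")) {
    cfg <- recon_config(grid, psf = s$psf, projector = s$proj,
                        sensitivity_method = m)
    sens <- compute_sensitivity(tr, s$g, cfg)
    expect_equal(sens$values, base$values, tolerance = 1e-6)
  }
  expect_error(compute_sensitivity(static_track(1)[0, ], s$g,
                                   recon_config(grid, psf = s$psf)), "empty")
})

test_that("sensitivity strategies agree for a translated pose", {
  g <- scanner_geometry(50, 16)
  grid <- voxel_grid(32, 2)
  # dense transverse sampling so the back-projection is smooth enough for
  # bilinear pose-resampling to track it
  psf <- psf_model(4, 2)
  proj <- projector_config(31, g$crystal_width)
  tr <- motion_track(c(0, 20), list(rt_translation(c(3.2, -1.7, 0)),
                                    rt_translation(c(3.2, -1.7, 0))))
  sens <- lapply(c("image_space_average", "projection_space_per_pose"),
                 function(m) {
                   compute_sensitivity(tr, g,
                                       recon_config(grid, psf = psf,
                                                    projector = proj,
                                                    sensitivity_method = m))
                 })
  core <- sens[[2]]$values > 0.5 * max(sens[[2]]$values)
  rel_rms <- sqrt(mean((sens[[1]]$values[core] - sens[[2]]$values[core])^2)) /
    sqrt(mean(sens[[2]]$values[core]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("static full-ring sensitivity has the ring's rotational symmetry", {
  g <- scanner_geometry(50, 16)
  proj <- projector_config(5, g$crystal_width)
  grid <- voxel_grid(33, 2)       # odd grid centred on the isocenter
  cfg <- recon_config(grid, psf = psf_model(0, 0), projector = proj)
  sens <- compute_sensitivity(NULL, g, cfg)$values
  rot90 <- t(sens)[, rev(seq_len(33))]          # exact 90-degree rotation
  expect_equal(sens, rot90, tolerance = 1e-9)
  expect_equal(sens, sens[rev(seq_len(33)), ], tolerance = 1e-9)
})

test_that("MLEM on noise-free static data: log-likelihood and NRMSE behave", {
  s <- tiny_setup(16)
  # single off-centre disc
  n <- 120
  grid_f <- voxel_grid(n, 0.5)
  co <- grid_coordinates(grid_f)
  act <- matrix(as.numeric((co$x - 8)^2 + (co$y + 5)^2 <= 36), n, n)
  ph <- structure(list(activity = pet_image(grid_f, act), attenuation = NULL,
                       description = "disc"), class = "phantom")
  tr <- static_track(2)
  lm <- expected_listmode(ph, tr, s$g, s$psf, s$proj, total_counts = 1e5)
  cfg <- recon_config(voxel_grid(32, 2), n_iterations = 20, n_subsets = 1,
                      psf = s$psf, projector = s$proj)
  rec <- lm_osem_sr(lm, tr, cfg)

  ll <- rec$trace$loglik
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))

  # NRMSE to the (downsampled, masked) ground truth strictly decreases
  truth <- resample_to_grid(ph$activity, cfg$grid)$values
  nrmse <- numeric(20)
  for (it in 1:20) {
    cfg_it <- recon_config(voxel_grid(32, 2), n_iterations = it, n_subsets = 1,
                           psf = s$psf, projector = s$proj)
    ri <- lm_osem_sr(lm, tr, cfg_it)
    sc <- sum(ri$image$values * truth) / sum(ri$image$values^2)
    nrmse[it] <- sqrt(mean((sc * ri$image$values - truth)^2)) /
      sqrt(mean(truth^2))
  }
  expect_true(all(diff(nrmse) < 0))
})

test_that("count consistency: total forward expectation converges to M", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spot_diameter = 4, spacing = 14,
                             pixel_size = 1)
  tr <- static_track(2)
  lm <- expected_listmode(ph, tr, s$g, s$psf, s$proj, total_counts = 5e4)
  cfg <- recon_config(voxel_grid(32, 2), n_iterations = 10, n_subsets = 1,
                      psf = s$psf, projector = s$proj)
  rec <- lm_osem_sr(lm, tr, cfg)
  g <- glance(rec)
  expect_equal(g$total_expected, g$n_events, tolerance = 0.01)
})

test_that("zero events reconstruct to the zero image", {
  s <- tiny_setup(16)
  lm <- structure(tibble::tibble(timestamp_ms = numeric(), det_a = integer(),
                                 det_b = integer(), lor = integer()),
                  class = c("petsr_listmode", "tbl_df", "tbl", "data.frame"),
                  geometry = s$g, duration_ms = 100,
                  pulse_train = pulse_train(0), seed = 1L)
  cfg <- recon_config(voxel_grid(16, 4), n_iterations = 2, psf = s$psf,
                      projector = s$proj)
  rec <- lm_osem_sr(lm, static_track(5), cfg)
  expect_equal(max(rec$image$values), 0)
})

test_that("reconstructions with both sensitivity methods agree", {
  g <- scanner_geometry(50, 64)
  psf <- psf_budget(4, g$crystal_width)
  proj <- projector_config(15, g$crystal_width)
  ph <- make_hotspot_phantom(n_spots = 4, spot_diameter = 4, spacing = 14,
                             pixel_size = 1)
  tr <- generate_motion("brownian", 1, n_frames = 8, seed = 3)
  lm <- simulate_listmode(ph, tr, g, psf, proj, total_counts = 2e5, seed = 6)
  rec <- lapply(c("image_space_average", "projection_space_per_pose"),
                function(m) {
                  cfg <- recon_config(voxel_grid(32, 2), n_iterations = 4,
                                      n_subsets = 2, psf = psf,
                                      projector = proj, sensitivity_method = m)
                  lm_osem_sr(lm, tr, cfg)$image$values
                })
  core <- rec[[2]] > 0.1 * max(rec[[2]])
  rel_rms <- sqrt(mean((rec[[1]][core] - rec[[2]][core])^2)) /
    sqrt(mean(rec[[2]][core]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("pose deduplication merges repeated poses losslessly", {
  tr <- generate_motion("linear", 1, n_frames = 50, bound = 5)
  dd <- petsr:::dedupe_poses(tr)
  expect_lt(length(dd$transforms), 15)     # ping-pong revisits poses
  expect_equal(sum(dd$weight), 1)
  # reconstruction of the frame list from pose ids matches the original track
  eul <- dplyr::bind_rows(lapply(dd$transforms[dd$pose_of_frame], rt_to_euler))
  expect_equal(eul$tx, tr$tx, tolerance = 0.011)
  expect_equal(eul$ty, tr$ty, tolerance = 0.011)
})

test_that("recon accessors expose trace and summary tibbles", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spot_diameter = 4, spacing = 14,
                             pixel_size = 1)
  tr <- static_track(3)
  lm <- simulate_listmode(ph, tr, s$g, s$psf, s$proj, total_counts = 1e4, seed = 2)
  bg <- matrix(FALSE, 24, 24); bg[2:5, 2:5] <- TRUE
  cfg <- recon_config(voxel_grid(24, 2), n_iterations = 3, n_subsets = 3,
                      psf = s$psf, projector = s$proj)
  rec <- lm_osem_sr(lm, tr, cfg, background_roi = bg)
  expect_equal(nrow(tidy(rec)), 3)
  expect_true(all(!is.na(tidy(rec)$bg_sd)))
  gl <- glance(rec)
  expect_equal(gl$n_events, nrow(lm))
  expect_s3_class(autoplot(rec), "ggplot")
})
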