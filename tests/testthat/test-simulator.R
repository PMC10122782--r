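test_that("hot-spot phantom geometry and activity accounting are exact", {
  ph <- make_hotspot_phantom(n_spots = 9, spot_diameter = 2.4, spacing = 12,
                             pixel_size = 0.25)
  expect_equal(nrow(ph$spot_centers), 9)
  # pairwise row/column centre distances equal the pitch
  sc <- ph$spot_centers
  row0 <- sort(sc$x[sc$y == 0])
  expect_equal(diff(row0), c(12, 12))
  col0 <- sort(sc$y[sc$x == 0])
  expect_equal(diff(col0), c(12, 12))

  # total activity by direct pixel summation
  v <- ph$activity$values
  co <- grid_coordinates(ph$activity$grid)
  disc_px <- 0L
  for (i in 1:9) {
    disc_px <- disc_px + sum((co$x - sc$x[i])^2 + (co$y - sc$y[i])^2 <= 1.2^2)
  }
  bg_px <- sum(v > 0) - disc_px
  expect_equal(sum(v), bg_px * 1 + disc_px * 10)

  # equal activities collapse to a constant over the support
  flat <- make_hotspot_phantom(spot_activity = 2, background_activity = 2)
  expect_equal(sort(unique(as.vector(flat$activity$values))), c(0, 2))

  expect_error(make_hotspot_phantom(spacing = 2), "overlapping")
  expect_error(make_hotspot_phantom(pixel_size = 1), "pixel_size")
})

test_that("rod phantom has both sectors with the stated rod spacing", {
  ph <- make_rod_phantom(c(3.2, 2.4), pixel_size = 0.25)
  expect_setequal(unique(ph$rod_centers$diameter), c(3.2, 2.4))

  # nearest-neighbour rod distance = 2 d within a sector by construction
  one <- make_rod_phantom(3.2, pixel_size = 0.32)
  rc <- one$rod_centers
  d <- as.matrix(dist(cbind(rc$x, rc$y)))
  diag(d) <- Inf
  expect_equal(min(d), 6.4)

  # rod pixel area approximates the analytic disc area for pixel = d/10
  ph10 <- make_rod_phantom(2.4, pixel_size = 0.24)
  rc10 <- ph10$rod_centers
  co <- grid_coordinates(ph10$activity$grid)
  v <- as.vector(ph10$activity$values)
  px_per_rod <- sum(v == 10) / nrow(rc10)
  expect_equal(px_per_rod * 0.24^2, pi * 1.2^2, tolerance = 0.1)
})

test_that("motion patterns respect the amplitude contract", {
  # zero amplitude: all identity
  for (p in petsr:::MOTION_PATTERNS) {
    tr <- generate_motion(p, 0, n_frames = 100)
    expect_equal(max(abs(as.matrix(tr[, c("tx", "ty", "tz", "rx", "ry", "rz")]))), 0)
  }
  expect_error(generate_motion("wobble", 1), "arg")
  expect_error(generate_motion("linear", 1, frame_rate = 45), "frame_rate")

  # linear: consecutive displacement norms all equal the step except reversals
  tr <- generate_motion("linear", 0.7, n_frames = 100, bound = 6)
  d <- sqrt(diff(tr$tx)^2 + diff(tr$ty)^2)
  expect_gt(mean(abs(d - 0.7) < 1e-9), 0.85)
  expect_true(all(d <= 2 * 0.7 + 1e-9))
  expect_lte(max(sqrt(tr$tx^2 + tr$ty^2)), 6 + 1e-9)

  # timestamps at 60 Hz
  tr60 <- generate_motion("circular", 1, n_frames = 100, frame_rate = 60)
  expect_equal(tr60$time_ms, (0:99) * 1000 / 60)
  # circular arc at the stated radius equals the amplitude step
  expect_equal(diff(tr60$rz)[1] * pi / 180 * 18, 1, tolerance = 1e-12)

  # spiral: per-frame step length equals the amplitude
  sp <- generate_motion("spiral", 0.5, n_frames = 100)
  dsp <- sqrt(diff(sp$tx)^2 + diff(sp$ty)^2)
  expect_equal(dsp, rep(0.5, 99), tolerance = 0.02)

  # random back-and-forth: fixed step length
  rb <- generate_motion("random_back_forth", 0.8, n_frames = 200, seed = 4)
  drb <- sqrt(diff(rb$tx)^2 + diff(rb$ty)^2)
  expect_true(all(abs(drb - 0.8) < 1e-9 | drb < 1e-9))
})

test_that("brownian step RMS converges to the amplitude", {
  tr <- generate_motion("brownian", 0.5, n_frames = 10000, seed = 99)
  steps2 <- diff(tr$tx)^2 + diff(tr$ty)^2
  expect_equal(sqrt(mean(steps2)), 0.5, tolerance = 0.05)
})

test_that("identical seeds give identical tracks and event streams", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spacing = 10, pixel_size = 0.5)
  tr1 <- generate_motion("brownian", 1, n_frames = 20, seed = 5)
  tr2 <- generate_motion("brownian", 1, n_frames = 20, seed = 5)
  expect_identical(tr1, tr2)
  lm1 <- simulate_listmode(ph, tr1, s$g, s$psf, s$proj, total_counts = 2e4, seed = 8)
  lm2 <- simulate_listmode(ph, tr2, s$g, s$psf, s$proj, total_counts = 2e4, seed = 8)
  expect_identical(as.data.frame(lm1), as.data.frame(lm2))
  expect_false(identical(
    as.data.frame(lm1),
    as.data.frame(simulate_listmode(ph, tr1, s$g, s$psf, s$proj,
                                    total_counts = 2e4, seed = 9))))
})

test_that("zero-activity phantom produces zero events", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spacing = 10, pixel_size = 0.5,
                             spot_activity = 0, background_activity = 0)
  lm <- simulate_listmode(ph, static_track(10), s$g, s$psf, s$proj,
                          total_counts = 100, seed = 1)
  expect_equal(nrow(lm), 0)
})

test_that("static per-LOR counts follow the Poisson forward model (chi-square)", {
  s <- tiny_setup(24)
  ph <- make_hotspot_phantom(n_spots = 4, spot_diameter = 4, spacing = 14,
                             pixel_size = 1)
  tr <- static_track(5)
  n_ev <- 1e6
  ex <- listmode_expectation(ph, tr, s$g, s$psf, s$proj, total_counts = n_ev)
  lam <- rowSums(ex$expected)
  lm <- simulate_listmode(ph, tr, s$g, s$psf, s$proj, total_counts = n_ev, seed = 12)
  obs <- tabulate(lm$lor, nbins = nrow(ex$lors))
  keep <- lam >= 5
  chi2 <- sum((obs[keep] - lam[keep])^2 / lam[keep])
  dof <- sum(keep)
  expect_gt(stats::pchisq(chi2, dof, lower.tail = FALSE), 0.01)
})

test_that("total event counts are Poisson-consistent over seeded runs", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spacing = 10, pixel_size = 0.5)
  n_target <- 5e3
  totals <- vapply(1:20, function(sd) {
    nrow(simulate_listmode(ph, static_track(3), s$g, s$psf, s$proj,
                           total_counts = n_target, seed = sd))
  }, numeric(1))
  expect_lt(abs(mean(totals) - n_target), 3 * sqrt(n_target))
})

test_that("motion equivariance: shifted phantom equals shifted track in expectation", {
  s <- tiny_setup(16)
  d <- c(3, -2)
  ph0 <- make_hotspot_phantom(n_spots = 1, spacing = 10, pixel_size = 0.5,
                              background_radius = 8)
  # same phantom values, grid origin shifted by d: the translated object
  ph_shift <- ph0
  ph_shift$activity <- pet_image(
    voxel_grid(ph0$activity$grid$dims, ph0$activity$grid$voxel_size,
               ph0$activity$grid$origin + d),
    ph0$activity$values)

  tr_static <- static_track(4)
  tr_shift <- motion_track(tr_static$time_ms,
                           replicate(4, rt_translation(c(d, 0)), simplify = FALSE))
  ex_a <- listmode_expectation(ph_shift, tr_static, s$g, s$psf, s$proj)
  ex_b <- listmode_expectation(ph0, tr_shift, s$g, s$psf, s$proj)
  expect_equal(ex_a$expected, ex_b$expected, tolerance = 1e-9)
})

test_that("events carry valid timestamps, detector pairs and sorted order", {
  s <- tiny_setup(16)
  ph <- make_hotspot_phantom(n_spots = 4, spacing = 10, pixel_size = 0.5)
  tr <- generate_motion("linear", 1, n_frames = 10)
  lm <- simulate_listmode(ph, tr, s$g, s$psf, s$proj, total_counts = 5e3, seed = 2)
  expect_true(!is.unsorted(lm$timestamp_ms))
  expect_true(all(lm$timestamp_ms >= 0 &
                    lm$timestamp_ms <= attr(lm, "duration_ms")))
  lors <- enumerate_lors(s$g)
  expect_true(all(lm$lor %in% lors$lor))
  expect_equal(lm$det_a, lors$det_a[lm$lor])
})
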