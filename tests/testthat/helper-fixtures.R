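# Shared fixtures: small geometries, random transforms, independent oracles.

small_geom <- function(n = 16, r = 50) scanner_geometry(ring_radius = r, n_detectors = n)

# random valid rigid transform (rotations up to ~20 deg, translations ~40 mm,
# the motion range of the phantom experiments)
random_transform <- function(rot_scale = 20, trans_scale = 40) {
  rt_from_euler(tx = stats::runif(1, -trans_scale, trans_scale),
                ty = stats::runif(1, -trans_scale, trans_scale),
                tz = stats::runif(1, -trans_scale, trans_scale),
                rx = stats::runif(1, -rot_scale, rot_scale),
                ry = stats::runif(1, -rot_scale, rot_scale),
                rz = stats::runif(1, -rot_scale, rot_scale))
}

# independent 4x4 homogeneous-matrix oracle
hom <- function(t) {
  m <- diag(4); m[1:3, 1:3] <- t$rotation; m[1:3, 4] <- t$translation; m
}

# dense-sampling line-integral oracle (step in mm)
quadrature_integral <- function(img, p1, p2, step = 0.002) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- ceiling(len / step)
  f <- (seq_len(n) - 0.5) / n
  pts <- cbind(p1[1] + f * (p2[1] - p1[1]), p1[2] + f * (p2[2] - p1[2]))
  g <- img$grid
  ix <- floor((pts[, 1] - g$origin[1]) / g$voxel_size[1] + 0.5)
  iy <- floor((pts[, 2] - g$origin[2]) / g$voxel_size[2] + 0.5)
  ok <- ix >= 0 & ix < g$dims[1] & iy >= 0 & iy < g$dims[2]
  sum(img$values[cbind(ix[ok] + 1, iy[ok] + 1)]) * len / n
}

random_image <- function(n = 32, voxel = 2) {
  pet_image(voxel_grid(n, voxel), matrix(stats::runif(n * n), n, n))
}

# tiny standard study objects used across recon/bench tests
tiny_setup <- function(n_det = 32, ring = 50) {
  g <- scanner_geometry(ring_radius = ring, n_detectors = n_det)
  psf <- psf_budget(4, g$crystal_width)
  proj <- projector_config(n_rays = 5, crystal_width = g$crystal_width)
  list(g = g, psf = psf, proj = proj)
}
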