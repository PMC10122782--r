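#' Ring scanner geometry
#'
#' A single-plane (2D) PET detector ring: `n_detectors` crystal centres lie
#' exactly on the circle of radius `ring_radius` in the z = 0 plane, uniformly
#' spaced, with the isocenter at the world origin. The crystal width sets the
#' transverse extent sampled by the multi-ray projector and hence the dominant
#' geometric resolution limit of the simulated system.
#'
#' @param ring_radius ring radius (mm).
#' @param n_detectors number of crystals (even, >= 8).
#' @param crystal_width crystal transverse width (mm); defaults to the full
#'   packing pitch `2 * pi * ring_radius / n_detectors`.
#' @param fov_radius field-of-view radius (mm) used to discard chords that
#'   miss the imaging region; defaults to `0.7 * ring_radius`.
#' @return An object of class `scanner_geometry`.
#' @examples
#' g <- scanner_geometry(ring_radius = 50, n_detectors = 64)
#' nrow(enumerate_lors(g))
#' @export
scanner_geometry <- function(ring_radius, n_detectors,
                             crystal_width = 2 * pi * ring_radius / n_detectors,
                             fov_radius = 0.7 * ring_radius) {
  stopifnot(ring_radius > 0, n_detectors >= 8, n_detectors %% 2 == 0,
            crystal_width > 0, fov_radius >= 0)
  structure(list(ring_radius = ring_radius,
                 n_detectors = as.integer(n_detectors),
                 crystal_width = crystal_width,
                 fov_radius = fov_radius),
            class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("<scanner_geometry> ring %g mm, %d detectors, crystal %.2f mm, FOV %g mm\n",
              x$ring_radius, x$n_detectors, x$crystal_width, x$fov_radius))
  invisible(x)
}

#' Detector crystal centres
#' @param g a `scanner_geometry`.
#' @return Tibble with `det` (1-based index), `x`, `y` (mm, z = 0 plane).
#' @export
detector_positions <- function(g) {
  stopifnot(inherits(g, "scanner_geometry"))
  ang <- 2 * pi * (seq_len(g$n_detectors) - 1) / g$n_detectors
  tibble::tibble(det = seq_len(g$n_detectors),
                 x = g$ring_radius * cos(ang),
                 y = g$ring_radius * sin(ang))
}

#' Enumerate lines of response
#'
#' One LOR per unordered detector pair whose chord passes within
#' `fov_radius` of the isocenter, in lexicographic order of the index pair.
#'
#' @param g a `scanner_geometry`.
#' @param fov_radius optional override of the geometry's FOV cut (mm).
#' @return Tibble with columns `lor` (1-based index into this ordering),
#'   `det_a`, `det_b`, endpoint coordinates `ax, ay, bx, by` (mm) and the
#'   chord's distance from the isocenter `d` (mm).
#' @export
enumerate_lors <- function(g, fov_radius = g$fov_radius) {
  stopifnot(inherits(g, "scanner_geometry"))
  pos <- detector_positions(g)
  pairs <- utils::combn(g$n_detectors, 2)
  a <- pairs[1, ]; b <- pairs[2, ]
  ax <- pos$x[a]; ay <- pos$y[a]; bx <- pos$x[b]; by <- pos$y[b]
  # distance from origin to the chord line |p1 x (p2-p1)| / |p2-p1|
  ux <- bx - ax; uy <- by - ay
  d <- abs(ax * uy - ay * ux) / sqrt(ux^2 + uy^2)
  keep <- d <= fov_radius + 1e-12
  out <- tibble::tibble(det_a = a[keep], det_b = b[keep],
                        ax = ax[keep], ay = ay[keep],
                        bx = bx[keep], by = by[keep], d = d[keep])
  out <- dplyr::arrange(out, .data$det_a, .data$det_b)
  dplyr::mutate(out, lor = dplyr::row_number(), .before = 1)
}

#' Regular voxel grid
#'
#' 2D in-plane grid; `origin` is the world coordinate of the CENTRE of voxel
#' index (0, 0) so that `world(index) = origin + index * voxel_size` with
#' 0-based indices and no implicit axis flips.
#'
#' @param dims length-2 integer voxel counts `(nx, ny)`.
#' @param voxel_size voxel pitch (mm), scalar or length-2.
#' @param origin world centre of voxel (0,0) (mm); default centres the grid on
#'   the isocenter.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size, origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- c(dims, dims)
  if (length(voxel_size) == 1L) voxel_size <- c(voxel_size, voxel_size)
  stopifnot(length(dims) == 2L, all(dims >= 1L), all(voxel_size > 0))
  if (is.null(origin)) origin <- -(dims - 1) * voxel_size / 2
  stopifnot(length(origin) == 2L)
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d voxels, %g x %g mm, origin (%g, %g) mm\n",
              x$dims[1], x$dims[2], x$voxel_size[1], x$voxel_size[2],
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Voxel-centre world coordinates
#' @param grid a `voxel_grid`.
#' @return Tibble with 0-based indices `ix, iy` and world coords `x, y` (mm),
#'   in column-major order matching the image value matrix.
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ix <- rep(0:(grid$dims[1] - 1), times = grid$dims[2])
  iy <- rep(0:(grid$dims[2] - 1), each = grid$dims[1])
  tibble::tibble(ix = ix, iy = iy,
                 x = grid$origin[1] + ix * grid$voxel_size[1],
                 y = grid$origin[2] + iy * grid$voxel_size[2])
}

#' Image on a voxel grid
#'
#' Activity (arbitrary units), sensitivity, or attenuation (mm^-1) values on a
#' regular grid. Values are stored as an `nx` x `ny` matrix whose first index
#' runs along x.
#'
#' @param grid a `voxel_grid`.
#' @param values numeric matrix `dims[1] x dims[2]`, or a scalar to fill.
#' @param nonneg require values >= 0 (activity/sensitivity); default TRUE.
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(grid, values = 0, nonneg = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$dims[1], grid$dims[2])
  values <- as.matrix(values)
  if (!all(dim(values) == grid$dims)) stop("values do not match grid dims")
  if (!all(is.finite(values))) stop("image values must be finite")
  if (nonneg && any(values < 0)) stop("image values must be >= 0")
  structure(list(grid = grid, values = values), class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image> %d x %d @ %g mm, range [%g, %g]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$voxel_size[1],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble pet_image
#' @export
as_tibble.pet_image <- function(x, ...) {
  out <- grid_coordinates(x$grid)
  out$value <- as.vector(x$values)
  out
}

#' Plot an image as a raster
#' @param object a `pet_image`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot pet_image
#' @export
autoplot.pet_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "value")
}

#' @export
plot.pet_image <- function(x, ...) print(autoplot(x, ...))

# bilinear interpolation of image values at world points (n x 2 matrix);
# points outside the grid return `outside`
interp_bilinear <- function(img, pts, outside = 0) {
  g <- img$grid
  fx <- (pts[, 1] - g$origin[1]) / g$voxel_size[1]
  fy <- (pts[, 2] - g$origin[2]) / g$voxel_size[2]
  nx <- g$dims[1]; ny <- g$dims[2]
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  inside <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  i0c <- pmin(pmax(i0, 0), nx - 2); j0c <- pmin(pmax(j0, 0), ny - 2)
  # clamp the fractional part too for points exactly on the far edge
  wxc <- pmin(pmax(fx - i0c, 0), 1); wyc <- pmin(pmax(fy - j0c, 0), 1)
  v <- img$values
  idx <- function(i, j) i + 1L + nx * j
  val <- (1 - wxc) * (1 - wyc) * v[idx(i0c, j0c)] +
    wxc * (1 - wyc) * v[idx(i0c + 1, j0c)] +
    (1 - wxc) * wyc * v[idx(i0c, j0c + 1)] +
    wxc * wyc * v[idx(i0c + 1, j0c + 1)]
  val[!inside] <- outside
  attr(val, "inside") <- inside
  val
}
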