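roi_indices <- function(img, roi) {
  if (is.logical(roi)) {
    if (length(roi) != length(img$values)) stop("ROI mask does not match grid")
    which(roi)
  } else {
    roi <- as.integer(roi)
    if (length(roi) == 0L || any(roi < 1L) || any(roi > length(img$values))) {
      stop("ROI indices out of range or empty")
    }
    roi
  }
}

#' Contrast-to-noise ratio
#'
#' CNR = (mean over the union of target ROIs - background mean) / background
#' standard deviation, the background standard deviation using the unbiased
#' (n - 1) estimator. Invariant under adding a constant to the image and
#' linear under multiplication.
#'
#' @param img a `pet_image`.
#' @param target_rois list of voxel index vectors (or logical masks), the
#'   active target regions.
#' @param background_roi voxel index vector or logical mask with >= 2 voxels,
#'   disjoint from the targets.
#' @return CNR (scalar).
#' @export
cnr <- function(img, target_rois, background_roi) {
  stopifnot(inherits(img, "pet_image"))
  if (!is.list(target_rois)) target_rois <- list(target_rois)
  tgt <- unique(unlist(lapply(target_rois, roi_indices, img = img)))
  bg <- roi_indices(img, background_roi)
  if (length(bg) < 2L) stop("background ROI needs >= 2 voxels")
  if (length(intersect(tgt, bg)) > 0L) stop("target and background ROIs overlap")
  sd_bg <- stats::sd(img$values[bg])
  if (sd_bg == 0) stop("zero background variance: CNR undefined")
  (mean(img$values[tgt]) - mean(img$values[bg])) / sd_bg
}

#' Structural similarity over a region of interest
#'
#' Single-window SSIM combining luminance, contrast and correlation terms:
#' `(2 mu_a mu_b + c1)(2 cov_ab + c2) / ((mu_a^2 + mu_b^2 + c1)(var_a + var_b + c2))`
#' over the ROI voxels of the two images. Bounded by 1 with equality for
#' identical ROIs (up to the regularised degeneracies). The default
#' regularisation constants are `(0.01 L)^2` and `(0.03 L)^2` with `L` the
#' dynamic range over both ROIs combined, so the defaults are symmetric in the
#' two images.
#'
#' @param img_a,img_b `pet_image`s on the same grid.
#' @param roi voxel index vector or logical mask (defaults to the whole grid).
#' @param c1,c2 positive regularisation constants.
#' @return SSIM (scalar).
#' @export
ssim <- function(img_a, img_b, roi = NULL, c1 = NULL, c2 = NULL) {
  stopifnot(inherits(img_a, "pet_image"), inherits(img_b, "pet_image"))
  if (!identical(img_a$grid$dims, img_b$grid$dims) ||
      !isTRUE(all.equal(img_a$grid$voxel_size, img_b$grid$voxel_size))) {
    stop("images are on different grids")
  }
  idx <- if (is.null(roi)) seq_along(img_a$values) else roi_indices(img_a, roi)
  a <- img_a$values[idx]; b <- img_b$values[idx]
  if (is.null(c1) || is.null(c2)) {
    l <- max(max(a) - min(a), max(b) - min(b), .Machine$double.eps)
    if (is.null(c1)) c1 <- (0.01 * l)^2
    if (is.null(c2)) c2 <- (0.03 * l)^2
  }
  stopifnot(c1 > 0, c2 > 0)
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / n; vb <- sum((b - mu_b)^2) / n
  cab <- sum((a - mu_a) * (b - mu_b)) / n
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' Multi-window SSIM
#'
#' Aggregates single-window SSIM over several windows, either supplied
#' explicitly or placed by seeded random selection of square windows centred
#' inside a small-structure mask. Reports the mean and standard deviation
#' across windows.
#'
#' @inheritParams ssim
#' @param windows list of ROIs (index vectors / logical masks); if NULL,
#'   `n_windows` square windows of `window_size` voxels are drawn with `seed`
#'   centred at voxels of `mask`.
#' @param mask logical grid mask of candidate window centres.
#' @param n_windows,window_size,seed window generation parameters
#'   (`window_size` is the in-plane side, default 11).
#' @return Tibble with `mean_ssim`, `sd_ssim`, `n_windows`.
#' @export
multi_window_ssim <- function(img_a, img_b, windows = NULL, mask = NULL,
                              n_windows = 20, window_size = 11, seed = 1L,
                              c1 = NULL, c2 = NULL) {
  if (is.null(windows)) {
    if (is.null(mask)) stop("supply windows or a mask for window placement")
    dims <- img_a$grid$dims
    half <- window_size %/% 2
    cand <- which(matrix(mask, dims[1], dims[2]), arr.ind = TRUE)
    cand <- cand[cand[, 1] > half & cand[, 1] <= dims[1] - half &
                   cand[, 2] > half & cand[, 2] <= dims[2] - half, , drop = FALSE]
    if (nrow(cand) == 0L) stop("mask leaves no room for windows")
    centers <- withr::with_seed(seed, {
      cand[sample.int(nrow(cand), n_windows, replace = nrow(cand) < n_windows), ,
           drop = FALSE]
    })
    windows <- lapply(seq_len(nrow(centers)), function(i) {
      ix <- centers[i, 1] + (-half:half)
      iy <- centers[i, 2] + (-half:half)
      as.vector(outer(ix, (iy - 1L) * dims[1], `+`))
    })
  }
  if (length(windows) < 2L) stop("need >= 2 windows")
  vals <- vapply(windows, function(wdw) ssim(img_a, img_b, wdw, c1, c2), numeric(1))
  tibble::tibble(mean_ssim = mean(vals), sd_ssim = stats::sd(vals),
                 n_windows = length(vals))
}

#' Sample a line profile through an image
#'
#' Bilinear interpolation at `n_samples` evenly spaced points along the
#' segment from `start` to `end` (world mm). Points outside the grid yield 0
#' and are flagged.
#'
#' @param img a `pet_image`.
#' @param start,end world coordinates (mm), length-2.
#' @param n_samples number of samples (>= 2).
#' @return Tibble of class `line_profile` with `s_mm` (distance along the
#'   segment), `x`, `y`, `value`, `inside`.
#' @export
line_profile <- function(img, start, end, n_samples = 201) {
  stopifnot(inherits(img, "pet_image"), n_samples >= 2)
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("degenerate segment")
  f <- seq(0, 1, length.out = n_samples)
  pts <- cbind(start[1] + f * (end[1] - start[1]),
               start[2] + f * (end[2] - start[2]))
  v <- interp_bilinear(img, pts)
  out <- tibble::tibble(s_mm = f * len, x = pts[, 1], y = pts[, 2],
                        value = as.numeric(v), inside = attr(v, "inside"))
  structure(out, class = c("line_profile", class(out)), length_mm = len)
}

#' @method autoplot line_profile
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance along profile (mm)", y = "value")
}

#' Mean peak-to-valley ratio of a line profile
#'
#' Profile values are interpolated at ground-truth peak positions (structure
#' centres) and valley positions (midpoints between structures), both given as
#' distances along the profile; the MPVR is the mean of peak/valley value
#' ratios over adjacent (peak, valley) pairs in position order. Positions come
#' from the known phantom geometry, not from peak detection. Invariant under
#' multiplying the profile by a positive constant.
#'
#' @param profile a `line_profile`.
#' @param peak_positions,valley_positions distances along the profile (mm).
#' @return MPVR (scalar).
#' @export
mpvr <- function(profile, peak_positions, valley_positions) {
  stopifnot(inherits(profile, "line_profile"),
            length(peak_positions) >= 1, length(valley_positions) >= 1)
  smax <- max(profile$s_mm)
  pos <- c(peak_positions, valley_positions)
  if (any(pos < 0) || any(pos > smax + 1e-9)) {
    stop("peak/valley positions must lie on the profile segment")
  }
  val_at <- function(s) stats::approx(profile$s_mm, profile$value, xout = s)$y
  ord <- order(pos)
  kind <- c(rep("peak", length(peak_positions)),
            rep("valley", length(valley_positions)))[ord]
  v <- val_at(pos[ord])
  ratios <- c()
  for (i in seq_len(length(v) - 1)) {
    if (kind[i] != kind[i + 1]) {
      pk <- if (kind[i] == "peak") v[i] else v[i + 1]
      vl <- if (kind[i] == "peak") v[i + 1] else v[i]
      if (vl <= 0) stop("valley value <= 0: peak-to-valley ratio undefined")
      ratios <- c(ratios, pk / vl)
    }
  }
  if (length(ratios) == 0L) stop("no adjacent (peak, valley) pairs")
  mean(ratios)
}

#' Downsample a fine reference image onto a coarser grid
#'
#' Grid-aligned averaging: each coarse voxel receives the mean of the fine
#' voxels whose centres fall inside it. Used to compare fine-grid ground truth
#' with a reconstruction before SSIM.
#'
#' @param img a `pet_image` on a fine grid.
#' @param grid target `voxel_grid` (coarser).
#' @return A `pet_image` on `grid`.
#' @export
resample_to_grid <- function(img, grid) {
  stopifnot(inherits(img, "pet_image"), inherits(grid, "voxel_grid"))
  co <- grid_coordinates(img$grid)
  ix <- round((co$x - grid$origin[1]) / grid$voxel_size[1])
  iy <- round((co$y - grid$origin[2]) / grid$voxel_size[2])
  ok <- ix >= 0 & ix < grid$dims[1] & iy >= 0 & iy < grid$dims[2]
  lin <- ix[ok] + 1L + grid$dims[1] * iy[ok]
  sums <- tapply(as.vector(img$values)[ok], lin, mean)
  v <- matrix(0, grid$dims[1], grid$dims[2])
  v[as.integer(names(sums))] <- sums
  pet_image(grid, v, nonneg = FALSE)
}
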