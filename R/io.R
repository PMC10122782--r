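#' Write / read a motion track (CSV)
#'
#' Plain-text CSV with one row per frame and mandatory header
#' `timestamp_ms, tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg`; angles are
#' Euler Z.Y.X intrinsic in degrees, stated in the file's comment header.
#'
#' @param track a `petsr_track`.
#' @param path file path.
#' @return `write_motion` returns `path` invisibly; `read_motion` returns a
#'   `petsr_track`.
#' @export
write_motion <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# petsr motion track; angles Euler Z.Y.X intrinsic, degrees", con)
  df <- data.frame(timestamp_ms = track$time_ms,
                   tx_mm = track$tx, ty_mm = track$ty, tz_mm = track$tz,
                   rx_deg = track$rx, ry_deg = track$ry, rz_deg = track$rz)
  utils::write.csv(format(df, digits = 15, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("timestamp_ms", "tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  if (!all(need %in% names(df))) {
    stop("motion file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(diff(df$timestamp_ms) <= 0)) stop("non-monotonic timestamps in motion file")
  out <- tibble::tibble(frame = seq_len(nrow(df)), time_ms = df$timestamp_ms,
                        tx = df$tx_mm, ty = df$ty_mm, tz = df$tz_mm,
                        rx = df$rx_deg, ry = df$ry_deg, rz = df$rz_deg)
  structure(out, class = c("petsr_track", class(out)))
}

#' Write / read list-mode data (CSV dialect)
#'
#' Event columns `timestamp_ms, det_a, det_b`; scanner geometry, duration and
#' the synchronisation pulse train are stored in `# key: value` comment lines
#' so a write-read round trip reproduces the stream and its metadata exactly.
#' Events are re-sorted by timestamp on read, with a warning, if needed.
#'
#' @param lm a `petsr_listmode`.
#' @param path file path.
#' @return `write_listmode` returns `path` invisibly; `read_listmode` a
#'   `petsr_listmode`.
#' @export
write_listmode <- function(lm, path) {
  g <- attr(lm, "geometry")
  pt <- attr(lm, "pulse_train")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("# ring_radius: %.12g", g$ring_radius),
            sprintf("# n_detectors: %d", g$n_detectors),
            sprintf("# crystal_width: %.12g", g$crystal_width),
            sprintf("# fov_radius: %.12g", g$fov_radius),
            sprintf("# duration_ms: %.12g", attr(lm, "duration_ms")),
            sprintf("# seed: %s", format(attr(lm, "seed"))),
            sprintf("# pulse_times_ms: %s",
                    paste(format(pt$pulse_times, digits = 15, trim = TRUE),
                          collapse = ";")),
            sprintf("# start_pattern_length: %d", pt$start_pattern_length))
  writeLines(meta, con)
  df <- data.frame(timestamp_ms = sprintf("%.9f", lm$timestamp_ms),
                   det_a = lm$det_a, det_b = lm$det_b)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^# ", key, ":"), metal, value = TRUE)
    if (length(hit) == 0) {
      if (required) stop("list-mode file is missing metadata field: ", key)
      return(NULL)
    }
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  g <- scanner_geometry(ring_radius = as.numeric(get("ring_radius")),
                        n_detectors = as.integer(get("n_detectors")),
                        crystal_width = as.numeric(get("crystal_width")),
                        fov_radius = as.numeric(get("fov_radius")))
  pulses <- as.numeric(strsplit(get("pulse_times_ms"), ";")[[1]])
  pt <- pulse_train(pulses, as.integer(get("start_pattern_length")))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("timestamp_ms", "det_a", "det_b")
  if (!all(need %in% names(df))) {
    stop("list-mode file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (is.unsorted(df$timestamp_ms)) {
    warning("events were not time-sorted; re-sorting")
    df <- df[order(df$timestamp_ms), ]
  }
  lors <- enumerate_lors(g)
  lid <- match(paste(df$det_a, df$det_b), paste(lors$det_a, lors$det_b))
  if (anyNA(lid)) stop("event references a detector pair outside the FOV LOR set")
  ev <- tibble::tibble(timestamp_ms = df$timestamp_ms,
                       det_a = as.integer(df$det_a),
                       det_b = as.integer(df$det_b), lor = lid)
  seed <- suppressWarnings(as.integer(get("seed", required = FALSE)))
  structure(ev, class = c("petsr_listmode", class(ev)),
            geometry = g, duration_ms = as.numeric(get("duration_ms")),
            pulse_train = pt, seed = seed)
}

#' Write / read a rigid transform (plain-text 4x4 homogeneous matrix)
#'
#' Row-major, whitespace-separated.
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform` a
#'   `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  m <- rt_to_matrix(transform)
  writeLines(apply(format(m, digits = 17), 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4L, 4L))) stop("transform file must be a 4x4 matrix")
  rt_from_matrix(unname(m))
}

#' Write / read paired calibration points (CSV)
#'
#' Columns `space_a_x_mm .. space_a_z_mm, space_b_x_mm .. space_b_z_mm`.
#' @param ps a `paired_points`.
#' @param path file path.
#' @return `write_paired_points` returns `path` invisibly; `read_paired_points`
#'   a `paired_points`.
#' @export
write_paired_points <- function(ps, path) {
  df <- data.frame(ps$points_a, ps$points_b)
  names(df) <- c(paste0("space_a_", c("x", "y", "z"), "_mm"),
                 paste0("space_b_", c("x", "y", "z"), "_mm"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_paired_points
#' @export
read_paired_points <- function(path) {
  df <- utils::read.csv(path)
  a <- as.matrix(df[, paste0("space_a_", c("x", "y", "z"), "_mm")])
  b <- as.matrix(df[, paste0("space_b_", c("x", "y", "z"), "_mm")])
  paired_points(unname(a), unname(b))
}

#' Write / read an image (NIfTI with mm voxel sizes)
#'
#' The voxel pitch goes into the NIfTI pixdim; the world coordinate of the
#' centre of voxel (0,0) is recorded in a plain-text sidecar
#' (`<path>.origin.txt`) so the world mapping round-trips exactly.
#'
#' @param img a `pet_image`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `write_image` returns `path` invisibly; `read_image` a `pet_image`.
#' @export
write_image <- function(img, path) {
  arr <- array(img$values, dim = c(img$grid$dims, 1L))
  ni <- RNifti::updateNifti(arr, template = list(
    pixdim = c(-1, img$grid$voxel_size, 1, 0, 0, 0, 0)))
  RNifti::writeNifti(ni, path)
  writeLines(format(img$grid$origin, digits = 17),
             paste0(path, ".origin.txt"))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ni <- RNifti::readNifti(path)
  arr <- as.array(ni)
  d <- dim(arr)
  vox <- RNifti::pixdim(ni)[1:2]
  origin_file <- paste0(path, ".origin.txt")
  origin <- if (file.exists(origin_file)) {
    as.numeric(readLines(origin_file))
  } else NULL
  grid <- voxel_grid(d[1:2], vox, origin)
  pet_image(grid, matrix(arr, d[1], d[2]), nonneg = FALSE)
}

#' Read / write a run configuration (YAML)
#'
#' Nested configuration used by the command-line interface; parse ->
#' serialise -> parse round-trips losslessly.
#'
#' @param config a named list.
#' @param path file path.
#' @return `read_config` returns the named list; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
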