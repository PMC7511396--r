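#' Multi-dimensional fluorescence image stack
#'
#' Container for raw image data with physical calibration. Pixels are stored
#' as a 5-D array `[T, Z, C, Y, X]` of non-negative intensities.
#'
#' @param pixels 5-D numeric array `[T, Z, C, Y, X]`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval minutes between frames (> 0).
#' @param channel_names character vector, one per channel.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, frame_interval = 18,
                        channel_names = NULL) {
  d <- dim(pixels)
  if (length(d) != 5) stop("pixels must be a 5-D array [T, Z, C, Y, X]")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[3]))
  if (length(channel_names) != d[3])
    stop("channel_names length must equal the channel dimension")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (min(pixels) < 0) stop("intensities must be non-negative")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "image_stack: T=%d Z=%d C=%d (%s) %dx%d px, %.3g um/px, %.3g min/frame\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ","), d[4], d[5],
    x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Planes are written in T-major, then Z, then C order as 16-bit pages;
#' dimensions, calibration and channel names go to `<path>.json` so the
#' stack round-trips through [read_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    i <- i + 1
    pages[[i]] <- pmin(pmax(stack$pixels[t, z, c, , ], 0), 65535) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(dims = as.list(stats::setNames(d, c("T", "Z", "C", "Y", "X"))),
               pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path .tif path (expects `<path>.json` sidecar alongside).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- unname(unlist(meta$dims))
  px <- array(0, dim = d)
  i <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    i <- i + 1
    px[t, z, c, , ] <- pages[[i]] * 65535
  }
  image_stack(px, pixel_size = meta$pixel_size,
              frame_interval = meta$frame_interval,
              channel_names = meta$channel_names)
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels integer matrix `[Y, X]` (0 = background).
#' @param path output path.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored in 16-bit")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path .tif path.
#' @return integer matrix `[Y, X]`.
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Serialize a synthetic scene to disk
#'
#' Writes the rendered time-lapse (TIFF + JSON sidecar), the ground-truth
#' table (cell id, frame, mitochondria count, engulfed count, fraction) and
#' the generator parameters (YAML) into a directory.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack <- render_timelapse(scene)
  write_image_stack(stack, file.path(dir, "timelapse.tif"))
  gt <- scene_ground_truth_table(scene)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  pars <- scene$params
  pars$induced_engulf_curve <- as.list(pars$induced_engulf_curve)
  yaml::write_yaml(unclass(pars), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Ground-truth table of a scene
#'
#' @param scene a `synthetic_scene`.
#' @return data.frame with cell, frame, mito_count, engulfed_count, fraction.
#' @export
scene_ground_truth_table <- function(scene) {
  rows <- list()
  for (ci in seq_along(scene$cells)) {
    n <- scene$cells[[ci]]$n_mito
    eng <- if (n > 0) colSums(scene$engulf[[ci]]) else
      rep(0L, scene$params$n_frames)
    rows[[ci]] <- data.frame(
      cell = ci, frame = seq_len(scene$params$n_frames),
      mito_count = n, engulfed_count = eng,
      fraction = if (n > 0) eng / n else NA_real_
    )
  }
  do.call(rbind, rows)
}
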