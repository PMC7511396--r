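#' Maximum intensity projection of one frame
#'
#' All quantification in this package runs on per-pixel maxima over z, never
#' per-plane.
#'
#' @param stack an [image_stack()].
#' @param frame frame index (1-based).
#' @return array `[C, Y, X]` with channel dimnames.
#' @export
max_project <- function(stack, frame = 1) {
  d <- dim(stack$pixels)
  if (frame < 1 || frame > d[1]) stop("frame out of range: ", frame)
  out <- array(0, dim = d[3:5],
               dimnames = list(stack$channel_names, NULL, NULL))
  for (c in seq_len(d[3])) {
    m <- stack$pixels[frame, 1, c, , ]
    if (d[2] > 1)
      for (z in 2:d[2]) m <- pmax(m, stack$pixels[frame, z, c, , ])
    out[c, , ] <- m
  }
  out
}

proj_channel <- function(projection, channel) {
  if (is.na(match(channel, dimnames(projection)[[1]])))
    stop("channel not present in projection: ", channel)
  projection[channel, , ]
}

otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (v - rng[1]) / diff(rng)
  EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng) + rng[1]
}

relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[out > 0] <- lut[out[out > 0]]
  out
}

size_filter <- function(labels, min_area) {
  if (max(labels) == 0) return(labels)
  sz <- tabulate(labels[labels > 0], nbins = max(labels))
  drop <- which(sz < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_contiguous(labels)
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian smoothing, automatic (Otsu) thresholding, minimum-area
#' filtering, and distance-transform watershed to split touching nuclei.
#' A blank image yields an empty label map (0 labels), not an error.
#'
#' @param projection `[C, Y, X]` array from [max_project()].
#' @param channel nuclear channel name.
#' @param min_area minimum object area in pixels.
#' @param blur_sigma Gaussian sigma for pre-smoothing (pixels).
#' @param split_touching split touching nuclei by watershed.
#' @return integer label matrix `[Y, X]` with contiguous labels, attribute
#'   `class` = "nucleus".
#' @export
segment_nuclei <- function(projection, channel = "nuclei", min_area = 25,
                           blur_sigma = 1, split_touching = TRUE) {
  img <- proj_channel(projection, channel)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask) || thr == min(sm)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "class_name") <- "nucleus"
    return(out)
  }
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  out <- size_filter(matrix(as.integer(labels), nrow(img), ncol(img)),
                     min_area)
  attr(out, "class_name") <- "nucleus"
  out
}

#' Segment cell regions (cytoplasm including projections) around nuclei
#'
#' Builds a cytoplasmic-intensity proxy (smoothed sum of the mitochondria
#' and lysosome channels), masks it with a robust background threshold, and
#' grows one region per nucleus by seeded propagation (Voronoi on the
#' intensity landscape). Every nucleus pixel belongs to its own cell and
#' cells are disjoint by construction.
#'
#' @param projection `[C, Y, X]` array.
#' @param nuclei nucleus label map from [segment_nuclei()].
#' @param cyto_channels channels summed into the cytoplasm proxy.
#' @param policy thresholding policy for the cytoplasm mask: "mad"
#'   (median + k * mad of the whole proxy; robust when background dominates)
#'   or "otsu".
#' @param k multiplier for the "mad" policy.
#' @param blur_sigma smoothing sigma for the proxy (pixels).
#' @return integer label matrix `[Y, X]`; labels match nucleus labels.
#'   Attribute `border_labels` lists cells touching the field border.
#' @export
segment_cells <- function(projection, nuclei,
                          cyto_channels = c("mitochondria", "lysosomes"),
                          policy = c("mad", "otsu"), k = 6, blur_sigma = 2) {
  policy <- match.arg(policy)
  if (max(nuclei) == 0) {
    out <- matrix(0L, dim(projection)[2], dim(projection)[3])
    attr(out, "class_name") <- "cell"
    attr(out, "border_labels") <- integer(0)
    return(out)
  }
  proxy <- Reduce(`+`, lapply(cyto_channels, proj_channel,
                              projection = projection))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(proxy), sigma = blur_sigma))
  thr <- if (policy == "mad")
    stats::median(sm) + k * stats::mad(sm) else otsu_threshold(sm)
  mask <- sm > thr | nuclei > 0
  labels <- EBImage::imageData(EBImage::propagate(
    x = EBImage::Image(sm / max(sm)), seeds = EBImage::Image(nuclei),
    mask = EBImage::Image(mask)))
  out <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  border <- unique(c(out[1, ], out[nrow(out), ], out[, 1], out[, ncol(out)]))
  attr(out, "class_name") <- "cell"
  attr(out, "border_labels") <- sort(border[border > 0])
  out
}

#' Segment small bright organelles within cell regions
#'
#' White top-hat background subtraction, Otsu thresholding on the in-cell
#' intensity histogram, minimum-area filtering, and assignment of every
#' object to its containing cell. Objects straddling two cells are split at
#' the cell boundary so organelle labels never cross cells.
#'
#' @param projection `[C, Y, X]` array.
#' @param cells cell label map from [segment_cells()].
#' @param class "mitochondrion" or "lysosome"; selects the default channel.
#' @param channel overrides the channel implied by `class`.
#' @param min_area minimum object area in pixels (default 3).
#' @param tophat_radius disc radius of the top-hat structuring element.
#' @return integer label matrix `[Y, X]` with contiguous labels; attribute
#'   `cell_of` maps each label to its cell.
#' @export
segment_organelles <- function(projection, cells,
                               class = c("mitochondrion", "lysosome"),
                               channel = NULL, min_area = 3,
                               tophat_radius = 9) {
  class <- match.arg(class)
  if (is.null(channel))
    channel <- switch(class, mitochondrion = "mitochondria",
                      lysosome = "lysosomes")
  img <- proj_channel(projection, channel)
  brush <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  th <- as.matrix(EBImage::whiteTopHat(EBImage::Image(img / 65535), brush)) *
    65535
  incell <- cells > 0
  if (!any(incell)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "class_name") <- class
    attr(out, "cell_of") <- integer(0)
    return(out)
  }
  thr <- otsu_threshold(th[incell])
  mask <- th > thr & incell
  labels <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(img), ncol(img))
  # split labels at cell boundaries: relabel by (object, cell) pair
  if (max(labels) > 0) {
    sel <- labels > 0
    key <- as.integer(factor(labels[sel] + (max(labels) + 1) *
                               as.double(cells[sel])))
    labels[sel] <- key
  }
  labels <- size_filter(labels, min_area)
  cell_of <- integer(max(labels))
  if (max(labels) > 0) {
    sel <- which(labels > 0)
    cell_of <- as.integer(tapply(cells[sel], labels[sel], function(v) v[1]))
  }
  attr(labels, "class_name") <- class
  attr(labels, "cell_of") <- cell_of
  labels
}

#' Count bright spots (puncta) per cell
#'
#' Local-maximum detection above a robust background threshold within cell
#' regions; adjacent maxima from one plateau are merged before counting.
#' Used for activated caspase-3 puncta.
#'
#' @param projection `[C, Y, X]` array.
#' @param cells cell label map.
#' @param channel spot channel name.
#' @param k threshold = background median + `k` * background mad.
#' @param blur_sigma smoothing sigma before maximum detection.
#' @return data.frame with cell_id, spot_count, positive (count >= 1).
#' @export
detect_spots <- function(projection, cells, channel, k = 8, blur_sigma = 1) {
  img <- proj_channel(projection, channel)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  bg <- cells == 0
  thr <- stats::median(sm[bg]) + k * stats::mad(sm[bg])
  dil <- as.matrix(EBImage::dilate(EBImage::Image(sm / max(sm)),
                                   EBImage::makeBrush(7, "disc"))) * max(sm)
  maxima <- (sm >= dil - 1e-9) & (sm > thr) & (cells > 0)
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(maxima * 1)))), nrow(img), ncol(img))
  ids <- sort(unique(cells[cells > 0]))
  counts <- integer(length(ids))
  if (max(lab) > 0) {
    sel <- which(lab > 0)
    spot_cell <- tapply(cells[sel], lab[sel], function(v) v[1])
    tab <- table(factor(spot_cell, levels = ids))
    counts <- as.integer(tab)
  }
  data.frame(cell_id = ids, spot_count = counts, positive = counts >= 1)
}

#' Percentage of cells positive for a marker
#'
#' A cell is positive when its mean marker intensity exceeds
#' `k` times the background median (pixels outside every cell).
#'
#' @param projection `[C, Y, X]` array.
#' @param cells cell label map; must contain at least one cell.
#' @param channel marker channel name.
#' @param k threshold multiplier on the background median.
#' @return percentage (0-100) of positive cells; attribute `per_cell` holds
#'   the per-cell table.
#' @export
marker_positive_fraction <- function(projection, cells, channel, k = 3) {
  if (max(cells) == 0)
    stop("marker_positive_fraction requires at least one segmented cell")
  img <- proj_channel(projection, channel)
  bg_med <- stats::median(img[cells == 0])
  ids <- sort(unique(cells[cells > 0]))
  means <- as.numeric(tapply(img[cells > 0], cells[cells > 0], mean))
  positive <- means > k * max(bg_med, .Machine$double.eps)
  pct <- 100 * sum(positive) / length(ids)
  attr(pct, "per_cell") <- data.frame(cell_id = ids, mean_intensity = means,
                                      positive = positive)
  pct
}
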