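# Cauchy-Crofton perimeter estimate from boundary crossings along 4
# direction families (0, 90, +-45 degrees); lower rasterization bias than
# counting boundary pixels.
crofton_perimeter <- function(mask) {
  mp <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(mp); nc <- ncol(mp)
  h <- sum(mp[, -1] != mp[, -nc])
  v <- sum(mp[-1, ] != mp[-nr, ])
  d1 <- sum(mp[-1, -1] != mp[-nr, -nc])
  d2 <- sum(mp[-1, -nc] != mp[-nr, -1])
  pi / 8 * (h + v + (d1 + d2) / sqrt(2))
}

# area, Crofton perimeter and second-moment axis ratio for every label
label_geometry <- function(labels) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), elongation = numeric(0),
                      degenerate = logical(0)))
  sel <- which(labels > 0)
  lab <- labels[sel]
  ys <- (sel - 1) %% nrow(labels) + 1
  xs <- (sel - 1) %/% nrow(labels) + 1
  out <- data.frame(label = seq_len(n), area_px = NA_real_,
                    perimeter_px = NA_real_, elongation = NA_real_,
                    degenerate = FALSE)
  idx_by_lab <- split(seq_along(lab), lab)
  for (key in names(idx_by_lab)) {
    i <- as.integer(key)
    ii <- idx_by_lab[[key]]
    y <- ys[ii]; x <- xs[ii]
    ybb <- range(y); xbb <- range(x)
    sub <- matrix(FALSE, diff(ybb) + 1, diff(xbb) + 1)
    sub[cbind(y - ybb[1] + 1, x - xbb[1] + 1)] <- TRUE
    out$area_px[i] <- length(ii)
    out$perimeter_px[i] <- crofton_perimeter(sub)
    if (length(ii) >= 2) {
      cv <- stats::cov(cbind(x, y)) + diag(2) / 12  # pixel extent correction
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      out$elongation[i] <- sqrt(max(ev) / max(min(ev), 1e-12))
    } else {
      out$elongation[i] <- 1
    }
    out$degenerate[i] <- diff(ybb) == 0 || diff(xbb) == 0
  }
  out
}

#' Per-cell shape metrics: roundness and elongation
#'
#' Roundness is the isoperimetric ratio `perimeter^2 / (4 pi area)` (circle
#' = 1, larger = less circular); elongation is the major/minor axis ratio of
#' the second-moment ellipse (circle = 1). Commercial high-content packages
#' use unpublished formulas with the opposite interpretation for
#' "roundness" (rounder cells scoring higher); set
#' `roundness_higher_is = "round"` to report the reciprocal convention.
#' One-pixel-wide regions are flagged and reported with a warning.
#'
#' @param cells cell label map.
#' @param pixel_size micrometres per pixel (areas/perimeters scale by it).
#' @param min_pixels cells below this size are dropped.
#' @param exclude_border drop cells flagged as touching the field border
#'   (attribute `border_labels` of the map), which would bias shape metrics.
#' @param roundness_higher_is "irregular" (isoperimetric, default) or
#'   "round" (reciprocal).
#' @return data.frame: cell_id, area_um2, perimeter_um, roundness,
#'   elongation, degenerate.
#' @export
cell_shape <- function(cells, pixel_size = 1, min_pixels = 10,
                       exclude_border = TRUE,
                       roundness_higher_is = c("irregular", "round")) {
  roundness_higher_is <- match.arg(roundness_higher_is)
  g <- label_geometry(cells)
  g <- g[g$area_px >= min_pixels, , drop = FALSE]
  if (exclude_border) {
    border <- attr(cells, "border_labels")
    if (!is.null(border)) g <- g[!(g$label %in% border), , drop = FALSE]
  }
  if (any(g$degenerate))
    warning(sum(g$degenerate), " degenerate (1-pixel-wide) cell regions; ",
            "their shape metrics are unreliable")
  roundness <- g$perimeter_px^2 / (4 * pi * g$area_px)
  if (roundness_higher_is == "round") roundness <- 1 / roundness
  data.frame(cell_id = g$label,
             area_um2 = g$area_px * pixel_size^2,
             perimeter_um = g$perimeter_px * pixel_size,
             roundness = roundness,
             elongation = g$elongation,
             degenerate = g$degenerate)
}

#' Per-cell mitochondrial statistics
#'
#' Number, mean area, mean intensity and interconnectivity of the
#' mitochondria assigned to each cell. Interconnectivity is the mean over a
#' cell's mitochondria of area/perimeter (micrometres; the convention of the
#' widely used ImageJ mitochondrial-morphology macro): fragmenting a fixed
#' total area into more, smaller objects lowers it. Cells with zero
#' mitochondria get `mito_count = 0` and `NA` interconnectivity (excluded
#' from group means downstream, never imputed).
#'
#' @param mito mitochondria label map from [segment_organelles()] (needs the
#'   `cell_of` attribute).
#' @param cells cell label map.
#' @param intensity optional `[Y, X]` matrix (e.g. the TMRM channel) for
#'   mean per-mitochondrion intensity.
#' @param pixel_size micrometres per pixel.
#' @param exclude_border drop border-touching cells.
#' @return data.frame: cell_id, mito_count, mito_mean_area_um2,
#'   mito_mean_intensity, interconnectivity_um.
#' @export
mito_stats_per_cell <- function(mito, cells, intensity = NULL, pixel_size = 1,
                                exclude_border = TRUE) {
  cell_of <- attr(mito, "cell_of")
  if (is.null(cell_of))
    stop("mito map lacks the cell_of attribute; use segment_organelles()")
  ids <- sort(unique(cells[cells > 0]))
  if (exclude_border) {
    border <- attr(cells, "border_labels")
    if (!is.null(border)) ids <- setdiff(ids, border)
  }
  g <- label_geometry(mito)
  g$cell <- cell_of[g$label]
  g$ratio_um <- (g$area_px / g$perimeter_px) * pixel_size
  if (!is.null(intensity)) {
    sel <- which(mito > 0)
    g$mean_intensity <-
      as.numeric(tapply(intensity[sel], mito[sel], mean))[g$label]
  } else g$mean_intensity <- rep(NA_real_, nrow(g))
  res <- data.frame(cell_id = ids, mito_count = 0L,
                    mito_mean_area_um2 = NA_real_,
                    mito_mean_intensity = NA_real_,
                    interconnectivity_um = NA_real_)
  for (i in seq_along(ids)) {
    sub <- g[!is.na(g$cell) & g$cell == ids[i], , drop = FALSE]
    res$mito_count[i] <- nrow(sub)
    if (nrow(sub) > 0) {
      res$mito_mean_area_um2[i] <- mean(sub$area_px) * pixel_size^2
      res$mito_mean_intensity[i] <- mean(sub$mean_intensity)
      res$interconnectivity_um[i] <- mean(sub$ratio_um)
    }
  }
  res
}

#' Normalize values to a control group's mean (percent of control)
#'
#' Each value is mapped to `100 * value / mean(control values)`, so the
#' control group mean is 100 by construction. Idempotent when re-applied
#' with the same control set.
#'
#' @param values numeric vector.
#' @param groups vector of group labels, same length.
#' @param control_group label of the control group.
#' @return numeric vector of percentages, same order as `values`.
#' @export
normalize_to_control <- function(values, groups, control_group = "control") {
  if (!control_group %in% groups)
    stop("control group not present: ", control_group)
  cm <- mean(values[groups == control_group], na.rm = TRUE)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be > 0 to normalize (got ", cm, ")")
  100 * values / cm
}

#' Background-subtracted mean in-mitochondria intensity per cell
#'
#' The per-cell mean intensity over mitochondrial pixels after subtracting
#' the median of non-cell pixels; with the TMRM channel this is the
#' membrane-potential (MMP) proxy, with the NpFR2 channel the mitochondrial
#' ROS proxy. Cells without mitochondria get `NA`.
#'
#' @param projection `[C, Y, X]` array.
#' @param cells cell label map.
#' @param mito mitochondria label map (with `cell_of` attribute).
#' @param channel intensity channel name.
#' @param exclude_border drop border-touching cells.
#' @return data.frame: cell_id, readout.
#' @export
intensity_readout_per_cell <- function(projection, cells, mito, channel,
                                       exclude_border = TRUE) {
  img <- proj_channel(projection, channel)
  bg <- stats::median(img[cells == 0])
  ids <- sort(unique(cells[cells > 0]))
  if (exclude_border) {
    border <- attr(cells, "border_labels")
    if (!is.null(border)) ids <- setdiff(ids, border)
  }
  cell_of <- attr(mito, "cell_of")
  res <- data.frame(cell_id = ids, readout = NA_real_)
  if (max(mito) > 0) {
    sel <- which(mito > 0)
    lab_mean <- tapply(img[sel] - bg, mito[sel], mean)
    lab_cell <- cell_of[as.integer(names(lab_mean))]
    for (i in seq_along(ids)) {
      v <- lab_mean[!is.na(lab_cell) & lab_cell == ids[i]]
      if (length(v) > 0) res$readout[i] <- mean(v)
    }
  }
  res
}
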