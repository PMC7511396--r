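#' Detect mitophagy events by mitochondrion-in-lysosome containment
#'
#' The live-assay rule: a mitophagy event is a mitochondrion whose
#' binarized max-projection mask is fully (100%) contained in a lysosome
#' mask. For each mitochondrion label the overlap fraction is the share of
#' its pixels covered by a single lysosome label (default) or by the union
#' of all lysosomes (`single_lysosome = FALSE`); an event is recorded when
#' the fraction reaches `overlap_threshold` (default 1, the strict 100%
#' rule; lower it on noisy real data). Each mitochondrion yields at most one
#' event per frame. Empty maps give an empty event list.
#'
#' @param mito mitochondria label map.
#' @param lyso lysosome label map on the same grid.
#' @param cells optional cell label map to attach cell ids (otherwise the
#'   `cell_of` attribute of `mito` is used when present).
#' @param overlap_threshold minimum overlap fraction for an event, in (0, 1].
#' @param single_lysosome require containment within one lysosome label
#'   rather than the union of the lysosome class.
#' @param frame frame index recorded in the output.
#' @return data.frame: cell_id, mito_label, lyso_label, frame,
#'   overlap_fraction (one row per event).
#' @export
detect_mitophagy_events <- function(mito, lyso, cells = NULL,
                                    overlap_threshold = 1,
                                    single_lysosome = TRUE, frame = 1L) {
  if (!all(dim(mito) == dim(lyso)))
    stop("mito and lyso maps must share the same grid")
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in (0, 1]")
  empty <- data.frame(cell_id = integer(0), mito_label = integer(0),
                      lyso_label = integer(0), frame = integer(0),
                      overlap_fraction = numeric(0))
  if (max(mito) == 0) return(empty)
  sel <- which(mito > 0)
  m <- mito[sel]
  l <- lyso[sel]
  sizes <- tabulate(m, nbins = max(m))
  rows <- list()
  ml <- l > 0
  if (any(ml)) {
    if (single_lysosome) {
      ov <- table(m[ml], l[ml])
      best_l <- as.integer(colnames(ov)[max.col(ov, ties.method = "first")])
      best_n <- apply(ov, 1, max)
      mids <- as.integer(rownames(ov))
    } else {
      cnt <- tapply(ml, m, sum)
      mids <- as.integer(names(cnt))
      best_n <- as.numeric(cnt)
      # representative lysosome: the single label with the largest overlap
      ov <- table(m[ml], l[ml])
      best_l <- as.integer(colnames(ov)[max.col(ov, ties.method = "first")])
      best_l <- best_l[match(mids, as.integer(rownames(ov)))]
    }
    frac <- best_n / sizes[mids]
    hit <- frac >= overlap_threshold
    if (any(hit)) {
      cell_of <- attr(mito, "cell_of")
      cid <- if (!is.null(cells)) {
        vapply(mids[hit], function(i) {
          px <- sel[m == i][1]
          as.integer(cells[px])
        }, integer(1))
      } else if (!is.null(cell_of)) {
        cell_of[mids[hit]]
      } else rep(NA_integer_, sum(hit))
      rows <- data.frame(cell_id = cid, mito_label = mids[hit],
                         lyso_label = best_l[hit], frame = as.integer(frame),
                         overlap_fraction = frac[hit])
      return(rows)
    }
  }
  empty
}

#' Per-cell mitophagy fraction from events
#'
#' `m = (distinct engulfed mitochondria) / (mitochondria count)` per cell.
#' Cells with zero mitochondria are excluded (with a message), never scored
#' as zero.
#'
#' @param events event table from [detect_mitophagy_events()].
#' @param mito_counts data.frame with cell_id and mito_count (e.g. from
#'   [mito_stats_per_cell()]).
#' @return data.frame: cell_id, mito_count, events, m.
#' @export
mitophagy_fraction_per_cell <- function(events, mito_counts) {
  zero <- mito_counts$mito_count == 0
  if (any(zero))
    message(sum(zero), " cells with zero mitochondria excluded from ",
            "mitophagy fractions")
  mc <- mito_counts[!zero, , drop = FALSE]
  n_ev <- vapply(mc$cell_id, function(id)
    length(unique(events$mito_label[events$cell_id == id])), integer(1))
  data.frame(cell_id = mc$cell_id, mito_count = mc$mito_count,
             events = n_ev, m = n_ev / mc$mito_count)
}

#' Assemble a mitophagy time-course from per-frame per-cell fractions
#'
#' Orders per-frame fractions on a minutes-from-start axis and summarizes
#' mean, SD and n per frame. Multiple fields of view are aligned by
#' acquisition index (no registration); unequal frame counts across fields
#' are truncated to the shortest with a warning. In the induced condition,
#' frames from `induction_time` (minutes) onward are flagged.
#'
#' @param fractions a data.frame with columns cell_id, frame, m — or a list
#'   of such data.frames (one per field of view).
#' @param condition "basal" or "induced".
#' @param frame_interval minutes between frames.
#' @param induction_time minutes from start at which induction begins.
#' @param group optional genotype label attached to the output.
#' @return object of class `mitophagy_timecourse`: data.frame with frame,
#'   minutes, mean_m, sd_m, n, condition, induced, group; the pooled
#'   per-cell table is kept in attribute `per_cell`.
#' @export
assemble_timecourse <- function(fractions, condition = c("basal", "induced"),
                                frame_interval = 18, induction_time = 0,
                                group = NA_character_) {
  condition <- match.arg(condition)
  if (is.data.frame(fractions)) fractions <- list(fractions)
  n_frames <- vapply(fractions, function(f) length(unique(f$frame)),
                     integer(1))
  if (min(n_frames) < 2)
    stop("a time-course needs at least 2 frames per field")
  if (length(unique(n_frames)) > 1) {
    warning("unequal frame counts across fields; truncating to the shortest (",
            min(n_frames), ")")
    fractions <- lapply(fractions, function(f)
      f[f$frame <= min(n_frames), , drop = FALSE])
  }
  for (i in seq_along(fractions)) fractions[[i]]$field <- i
  pooled <- do.call(rbind, fractions)
  frames <- sort(unique(pooled$frame))
  minutes <- (frames - 1) * frame_interval
  agg <- data.frame(
    frame = frames, minutes = minutes,
    mean_m = as.numeric(tapply(pooled$m, pooled$frame, mean)),
    sd_m = as.numeric(tapply(pooled$m, pooled$frame, stats::sd)),
    n = as.integer(tapply(pooled$m, pooled$frame, length)),
    condition = condition,
    induced = condition == "induced" & minutes >= induction_time,
    group = group
  )
  attr(agg, "per_cell") <- pooled
  class(agg) <- c("mitophagy_timecourse", "data.frame")
  agg
}

#' Integrated Tomm20 amount per cell (fixed-assay mitophagy readout)
#'
#' Sum of background-subtracted Tomm20 intensity over each cell region
#' (background = median of non-cell pixels). Direction: a higher Tomm20
#' amount means less mitochondrial clearance, i.e. less mitophagy.
#'
#' @param projection `[C, Y, X]` array of the fixed stain.
#' @param cells cell label map.
#' @param channel Tomm20 channel name.
#' @param exclude_border drop border-touching cells.
#' @return data.frame: cell_id, tomm20_amount.
#' @export
tomm20_loss_readout <- function(projection, cells, channel = "tomm20",
                                exclude_border = TRUE) {
  img <- proj_channel(projection, channel)
  bg <- stats::median(img[cells == 0])
  ids <- sort(unique(cells[cells > 0]))
  if (exclude_border) {
    border <- attr(cells, "border_labels")
    if (!is.null(border)) ids <- setdiff(ids, border)
  }
  amount <- vapply(ids, function(id) sum(img[cells == id] - bg), numeric(1))
  data.frame(cell_id = ids, tomm20_amount = amount)
}

#' LC3/Tomm20 colocalization count per cell (fixed-assay validation)
#'
#' Segments LC3 puncta and Tomm20 objects within cells, then applies the
#' same containment rule as the live assay: a Tomm20 object colocalizes when
#' its mask is contained (to `overlap_threshold`) in an LC3 punctum.
#'
#' @param projection `[C, Y, X]` array with both channels.
#' @param cells cell label map.
#' @param tomm20_channel,lc3_channel channel names.
#' @param overlap_threshold containment threshold, as in
#'   [detect_mitophagy_events()].
#' @param min_area,tophat_radius passed to [segment_organelles()].
#' @return data.frame: cell_id, tomm20_count, colocalized, fraction.
#' @export
lc3_tomm20_colocalization <- function(projection, cells,
                                      tomm20_channel = "tomm20",
                                      lc3_channel = "lc3",
                                      overlap_threshold = 1,
                                      min_area = 3, tophat_radius = 9) {
  tomm <- segment_organelles(projection, cells, class = "mitochondrion",
                             channel = tomm20_channel, min_area = min_area,
                             tophat_radius = tophat_radius)
  lc3 <- segment_organelles(projection, cells, class = "lysosome",
                            channel = lc3_channel, min_area = min_area,
                            tophat_radius = tophat_radius)
  ev <- detect_mitophagy_events(tomm, lc3,
                                overlap_threshold = overlap_threshold)
  counts <- mito_stats_per_cell(tomm, cells)[, c("cell_id", "mito_count")]
  names(counts)[2] <- "tomm20_count"
  counts$colocalized <- vapply(counts$cell_id, function(id)
    length(unique(ev$mito_label[ev$cell_id == id])), integer(1))
  counts$fraction <- ifelse(counts$tomm20_count > 0,
                            counts$colocalized / counts$tomm20_count,
                            NA_real_)
  counts
}
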