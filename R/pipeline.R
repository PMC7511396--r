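#' Build a run configuration
#'
#' One configuration object drives each end-to-end run; it is fully
#' serialized (with the package version and seeds) into every output
#' directory, so reruns from the written config are bit-identical.
#'
#' @param inputs character vector of stack paths (TIFF written by
#'   [write_image_stack()]) — or a list of `synthetic_scene` objects.
#' @param out_dir output directory.
#' @param channel_map named list mapping roles (nuclei, mitochondria,
#'   lysosomes, ...) to channel names in the inputs.
#' @param overlap_threshold mitophagy containment threshold.
#' @param single_lysosome containment within one lysosome vs the class union.
#' @param min_area,tophat_radius organelle segmentation parameters (pixels).
#' @param condition "basal" or "induced" (live assay metadata).
#' @param induction_time minutes; induced frames flagged from here on.
#' @param group genotype label for the run.
#' @param correction multiple-comparison correction for downstream stats.
#' @param seed integer seed recorded with the run.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, out_dir,
                       channel_map = list(nuclei = "nuclei",
                                          mitochondria = "mitochondria",
                                          lysosomes = "lysosomes"),
                       overlap_threshold = 1, single_lysosome = TRUE,
                       min_area = 3, tophat_radius = 9,
                       condition = "basal", induction_time = 0,
                       group = "control", correction = "sidak", seed = 1L) {
  cfg <- list(inputs = inputs, out_dir = out_dir, channel_map = channel_map,
              overlap_threshold = overlap_threshold,
              single_lysosome = single_lysosome, min_area = min_area,
              tophat_radius = tophat_radius, condition = condition,
              induction_time = induction_time, group = group,
              correction = correction, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_provenance <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- unclass(cfg)
  ser$inputs <- if (is.character(cfg$inputs)) cfg$inputs
                else sprintf("<in-memory synthetic scene %d>",
                             seq_along(cfg$inputs))
  ser$package_version <- as.character(utils::packageVersion("mitoquant"))
  yaml::write_yaml(ser, file.path(dir, "config.yaml"))
  invisible(dir)
}

log_line <- function(con, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n", file = con,
      append = TRUE)
}

resolve_inputs <- function(cfg) {
  if (is.character(cfg$inputs)) {
    missing <- cfg$inputs[!file.exists(cfg$inputs)]
    if (length(missing))
      stop("input stack(s) not found: ", paste(missing, collapse = ", "))
    lapply(cfg$inputs, read_image_stack)
  } else if (length(cfg$inputs) > 0 &&
             inherits(cfg$inputs[[1]], "synthetic_scene")) {
    cfg$inputs
  } else if (length(cfg$inputs) == 0) {
    stop("empty input list: nothing to analyse")
  } else stop("inputs must be stack paths or synthetic scenes")
}

check_channels <- function(stack, cfg, roles) {
  for (role in roles) {
    ch <- cfg$channel_map[[role]]
    if (is.null(ch))
      stop("channel map is missing the '", role, "' role")
    if (!ch %in% stack$channel_names)
      stop("channel '", ch, "' (role ", role, ") not present in input; ",
           "available: ", paste(stack$channel_names, collapse = ", "))
  }
}

segment_frame <- function(projection, cfg) {
  cm <- cfg$channel_map
  nuclei <- segment_nuclei(projection, channel = cm$nuclei)
  cells <- segment_cells(projection, nuclei,
                         cyto_channels = c(cm$mitochondria, cm$lysosomes))
  mito <- segment_organelles(projection, cells, class = "mitochondrion",
                             channel = cm$mitochondria,
                             min_area = cfg$min_area,
                             tophat_radius = cfg$tophat_radius)
  lyso <- segment_organelles(projection, cells, class = "lysosome",
                             channel = cm$lysosomes,
                             min_area = cfg$min_area,
                             tophat_radius = cfg$tophat_radius)
  list(nuclei = nuclei, cells = cells, mito = mito, lyso = lyso)
}

# one field of view of the live assay: per-frame segmentation, events and
# per-cell fractions. Scenes are rendered frame by frame so memory stays at
# one frame; the segmentation parameters are shared between basal and
# induced runs (induction is metadata only).
live_field <- function(input, cfg, field_id, logcon = NULL) {
  is_scene <- inherits(input, "synthetic_scene")
  n_frames <- if (is_scene) input$params$n_frames else dim(input$pixels)[1]
  static <- if (is_scene) render_static(input) else NULL
  events <- list(); fractions <- list()
  for (t in seq_len(n_frames)) {
    proj <- if (is_scene) render_projection(input, t, static = static)
            else max_project(input, t)
    seg <- segment_frame(proj, cfg)
    ev <- detect_mitophagy_events(seg$mito, seg$lyso, cells = seg$cells,
                                  overlap_threshold = cfg$overlap_threshold,
                                  single_lysosome = cfg$single_lysosome,
                                  frame = t)
    counts <- mito_stats_per_cell(seg$mito, seg$cells)[,
      c("cell_id", "mito_count")]
    fr_tab <- suppressMessages(mitophagy_fraction_per_cell(ev, counts))
    fr_tab$frame <- t
    ev$field <- field_id
    fr_tab$field <- field_id
    events[[t]] <- ev
    fractions[[t]] <- fr_tab
    if (!is.null(logcon))
      log_line(logcon, sprintf(
        "field %d frame %d: %d cells, %d mito, %d lyso, %d events",
        field_id, t, max(seg$cells), max(seg$mito), max(seg$lyso), nrow(ev)))
  }
  list(events = do.call(rbind, events), fractions = do.call(rbind, fractions))
}

#' Run the live mitophagy assay end to end
#'
#' For every input field: per-frame maximum projection, nucleus/cell/
#' organelle segmentation, 100%-overlap event detection and per-cell
#' fractions; then a pooled time-course. Writes events.csv,
#' fractions.csv, timecourse.csv, config.yaml and run.log into
#' `cfg$out_dir`. Deterministic given config and inputs.
#'
#' @param cfg a [run_config()]. Inputs need nuclei, mitochondria and
#'   lysosome channels (checked up front, failure names the file/channel).
#' @return the `mitophagy_timecourse`, invisibly; side effect: CSV outputs.
#' @export
run_live_mitophagy <- function(cfg) {
  inputs <- resolve_inputs(cfg)
  if (!inherits(inputs[[1]], "synthetic_scene")) {
    for (i in seq_along(inputs))
      check_channels(inputs[[i]], cfg,
                     c("nuclei", "mitochondria", "lysosomes"))
  }
  write_provenance(cfg, cfg$out_dir)
  logfile <- file.path(cfg$out_dir, "run.log")
  unlink(logfile)
  log_line(logfile, "live mitophagy run:", length(inputs), "fields, condition",
           cfg$condition)
  res <- lapply(seq_along(inputs), function(i)
    live_field(inputs[[i]], cfg, i, logcon = logfile))
  events <- do.call(rbind, lapply(res, `[[`, "events"))
  fractions <- do.call(rbind, lapply(res, `[[`, "fractions"))
  frame_interval <- if (inherits(inputs[[1]], "synthetic_scene"))
    inputs[[1]]$params$frame_interval else inputs[[1]]$frame_interval
  tc <- assemble_timecourse(
    split(fractions, fractions$field),
    condition = cfg$condition, frame_interval = frame_interval,
    induction_time = cfg$induction_time, group = cfg$group)
  utils::write.csv(events, file.path(cfg$out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(fractions, file.path(cfg$out_dir, "fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tc), file.path(cfg$out_dir, "timecourse.csv"),
                   row.names = FALSE)
  log_line(logfile, "done:", nrow(events), "events,",
           nrow(fractions), "cell-frames")
  invisible(tc)
}

#' Run the morphology assay end to end
#'
#' Segments frame 1 of every input, computes per-cell shape and
#' mitochondrial statistics, and writes per-cell and per-field summary CSVs.
#'
#' @param cfg a [run_config()].
#' @return data.frame of per-cell records (column `field` identifies the
#'   input), invisibly.
#' @export
run_morphology <- function(cfg) {
  inputs <- resolve_inputs(cfg)
  write_provenance(cfg, cfg$out_dir)
  logfile <- file.path(cfg$out_dir, "run.log")
  unlink(logfile)
  per_cell <- list()
  for (i in seq_along(inputs)) {
    input <- inputs[[i]]
    is_scene <- inherits(input, "synthetic_scene")
    if (!is_scene) check_channels(input, cfg,
                                  c("nuclei", "mitochondria", "lysosomes"))
    stack <- if (is_scene) render_timelapse_first_frame(input) else input
    proj <- max_project(stack, 1)
    ps <- stack$pixel_size
    seg <- segment_frame(proj, cfg)
    shape <- cell_shape(seg$cells, pixel_size = ps)
    mstats <- mito_stats_per_cell(
      seg$mito, seg$cells,
      intensity = proj_channel(proj, cfg$channel_map$mitochondria),
      pixel_size = ps)
    rec <- merge(shape, mstats, by = "cell_id")
    rec$field <- i
    rec$group <- cfg$group
    per_cell[[i]] <- rec
    log_line(logfile, sprintf("field %d: %d cells, %d mitochondria",
                              i, nrow(rec), sum(rec$mito_count)))
  }
  out <- do.call(rbind, per_cell)
  utils::write.csv(out, file.path(cfg$out_dir, "cells.csv"),
                   row.names = FALSE)
  summ <- do.call(rbind, lapply(split(out, out$field), function(d)
    data.frame(field = d$field[1], group = d$group[1], n_cells = nrow(d),
               mean_mito_count = mean(d$mito_count),
               mean_interconnectivity = mean(d$interconnectivity_um,
                                             na.rm = TRUE),
               mean_roundness = mean(d$roundness),
               mean_elongation = mean(d$elongation))))
  utils::write.csv(summ, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out)
}

# single-frame render wrapped as a stack (keeps run_morphology uniform)
render_timelapse_first_frame <- function(scene) {
  fr <- render_frame(scene, 1)
  px <- array(fr, dim = c(1, dim(fr)))
  image_stack(px, pixel_size = scene$params$pixel_size,
              frame_interval = scene$params$frame_interval,
              channel_names = dimnames(fr)[[2]])
}

#' Run the ATP partitioning assay end to end
#'
#' Reads plate tables (CSV with columns well, condition, luminescence and
#' optional timepoint/group), computes the OXPHOS/glycolysis partition per
#' timepoint x group, and the switch day per group. Writes partitions.csv
#' and config.yaml.
#'
#' @param cfg a [run_config()] whose `inputs` are plate CSV paths — or a
#'   list of `atp_plate` data.frames.
#' @return data.frame of partitions per timepoint x group, invisibly.
#' @export
run_metabolics <- function(cfg) {
  plates <- if (is.character(cfg$inputs)) {
    missing <- cfg$inputs[!file.exists(cfg$inputs)]
    if (length(missing))
      stop("plate file(s) not found: ", paste(missing, collapse = ", "))
    lapply(cfg$inputs, utils::read.csv)
  } else cfg$inputs
  write_provenance(cfg, cfg$out_dir)
  rows <- lapply(plates, function(pl) {
    if (!"untreated" %in% pl$condition)
      stop("plate without untreated wells: the partition is undefined")
    part <- atp_partition(pl)
    data.frame(
      timepoint = if ("timepoint" %in% names(pl)) pl$timepoint[1] else NA,
      group = if ("group" %in% names(pl)) pl$group[1] else NA,
      pct_oxphos = part$pct_oxphos, pct_glycolysis = part$pct_glycolysis,
      pct_residual_both = part$pct_residual_both,
      untreated_mean = part$untreated_mean,
      flags = paste(part$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(cfg$out_dir, "partitions.csv"),
                   row.names = FALSE)
  invisible(out)
}
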