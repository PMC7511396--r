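# small scenes shared across tests: desk-scale versions of the default
# (day-27 control) conditions, sized so a test runs in seconds

tiny_params <- function(seed = 1L, ...) {
  args <- list(n_cells = 6, mito_per_cell_mean = 10, lyso_per_cell_mean = 4,
               n_frames = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_params, args)
}

noise_free <- list(gaussian_sd = 0, poisson_scale = 0)

# rasterize a filled shape from an indicator function on pixel centres
raster_shape <- function(f, ny = 161, nx = 161) {
  xs <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny) - 0.5, times = nx), ny, nx)
  m <- matrix(0L, ny, nx)
  m[f(xs, ys)] <- 1L
  m
}

raster_disk <- function(r, cx = 80, cy = 80, ny = 161, nx = 161)
  raster_shape(function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2, ny, nx)

# total engulfed count of a scene at one frame (ground truth)
truth_engulfed <- function(scene, frame)
  sum(vapply(scene$engulf, function(E)
    if (nrow(E)) sum(E[, frame]) else 0L, numeric(1)))

# segmentation of one rendered frame, as the pipeline would run it
segment_scene_frame <- function(scene, frame = 1, static = NULL) {
  proj <- render_projection(scene, frame, static = static)
  nuclei <- segment_nuclei(proj)
  cells <- segment_cells(proj, nuclei)
  list(proj = proj, nuclei = nuclei, cells = cells,
       mito = segment_organelles(proj, cells, "mitochondrion"),
       lyso = segment_organelles(proj, cells, "lysosome"))
}
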