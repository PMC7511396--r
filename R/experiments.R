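#' Basal mitophagy recovery experiment on synthetic scenes
#'
#' Generates replicate synthetic time-lapse scenes at a known per-frame
#' engulfment probability, runs the full segmentation + 100%-overlap
#' pipeline on every frame, and returns the grand mean per-cell mitophagy
#' fraction together with its binomial standard error under the generator
#' rate (the oracle for recovery: the estimate should sit within ~2 SE of
#' the rate).
#'
#' @param rate per-mitochondrion per-frame engulfment probability.
#' @param seeds integer vector, one scene per seed (replicate fields).
#' @param n_cells,mito_per_cell_mean,n_frames scene dimensions.
#' @param ... further arguments to [scene_params()].
#' @return list: `grand_mean` (mean of per-cell per-frame fractions), `se`
#'   (binomial SE of that estimator at `rate`), `n_units` (cell-frames),
#'   `n_mito_obs` (total mitochondrion observations), `fractions` (table).
#' @export
recover_basal_rate <- function(rate, seeds, n_cells = 50,
                               mito_per_cell_mean = 20, n_frames = 10, ...) {
  frs <- lapply(seeds, function(s) {
    sc <- generate_scene(scene_params(
      n_cells = n_cells, mito_per_cell_mean = mito_per_cell_mean,
      n_frames = n_frames, basal_engulf_prob = rate, seed = s, ...))
    measure_scene_fractions(sc)
  })
  fractions <- do.call(rbind, frs)
  summarize_recovery(fractions, rate)
}

#' Induced mitophagy recovery experiment
#'
#' Induced condition: the engulfment probability follows a per-frame curve
#' (basal before induction, then the induced level). The control-like curve
#' holds a sustained plateau at `level`; the estimate is the grand mean over
#' plateau frames.
#'
#' @param level post-induction plateau engulfment probability.
#' @param seeds integer vector of scene seeds.
#' @param n_cells,mito_per_cell_mean,n_frames scene dimensions.
#' @param induction_frame first frame at the induced level.
#' @param basal pre-induction engulfment probability.
#' @param ... further arguments to [scene_params()].
#' @return as [recover_basal_rate()], computed over plateau frames only,
#'   plus `series` (per-frame mean fractions).
#' @export
recover_induced_plateau <- function(level, seeds, n_cells = 50,
                                    mito_per_cell_mean = 20, n_frames = 6,
                                    induction_frame = 3, basal = 0.09, ...) {
  curve <- c(rep(basal, induction_frame - 1),
             rep(level, n_frames - induction_frame + 1))
  frs <- lapply(seeds, function(s) {
    sc <- generate_scene(scene_params(
      n_cells = n_cells, mito_per_cell_mean = mito_per_cell_mean,
      n_frames = n_frames, induced_engulf_curve = curve, seed = s, ...))
    measure_scene_fractions(sc)
  })
  fractions <- do.call(rbind, frs)
  series <- tapply(fractions$m, fractions$frame, mean)
  plateau <- fractions[fractions$frame >= induction_frame, , drop = FALSE]
  out <- summarize_recovery(plateau, level)
  out$series <- data.frame(frame = as.integer(names(series)),
                           mean_m = as.numeric(series))
  out
}

#' Measure one synthetic time-lapse with the live mitophagy pipeline
#'
#' Renders each frame's maximum projection, segments nuclei, cells,
#' mitochondria and lysosomes, detects 100%-overlap events, and returns the
#' per-cell per-frame fraction table.
#'
#' @param scene a `synthetic_scene`.
#' @param overlap_threshold containment threshold for an event.
#' @return data.frame: cell_id, mito_count, events, m, frame.
#' @export
measure_scene_fractions <- function(scene, overlap_threshold = 1) {
  static <- render_static(scene)
  out <- vector("list", scene$params$n_frames)
  for (t in seq_len(scene$params$n_frames)) {
    proj <- render_projection(scene, t, static = static)
    nuclei <- segment_nuclei(proj)
    cells <- segment_cells(proj, nuclei)
    mito <- segment_organelles(proj, cells, "mitochondrion")
    lyso <- segment_organelles(proj, cells, "lysosome")
    ev <- detect_mitophagy_events(mito, lyso,
                                  overlap_threshold = overlap_threshold,
                                  frame = t)
    counts <- mito_stats_per_cell(mito, cells)[, c("cell_id", "mito_count")]
    fr <- suppressMessages(mitophagy_fraction_per_cell(ev, counts))
    fr$frame <- t
    out[[t]] <- fr
  }
  do.call(rbind, out)
}

# grand mean of per-cell fractions and the binomial SE of that estimator
# when every mitochondrion is an independent Bernoulli(rate) draw
summarize_recovery <- function(fractions, rate) {
  list(grand_mean = mean(fractions$m),
       se = sqrt(rate * (1 - rate) * sum(1 / fractions$mito_count)) /
         nrow(fractions),
       n_units = nrow(fractions),
       n_mito_obs = sum(fractions$mito_count),
       fractions = fractions)
}

#' Mitochondrial-number normalization experiment
#'
#' Generates control scenes at a reference mitochondria-per-cell mean and
#' mutant scenes with the mean scaled by `ratio`, segments single frames,
#' and normalizes the mutant per-cell counts to the control mean (percent of
#' control).
#'
#' @param ratio mutant/control mitochondria count ratio.
#' @param seeds integer vector; one control and one mutant scene per seed.
#' @param n_cells cells per scene.
#' @param ref_mean control mitochondria-per-cell mean.
#' @param ... further arguments to [scene_params()].
#' @return list: `pct_of_control` (mutant mean as percent of control),
#'   `per_cell` (counts with group labels).
#' @export
recover_count_ratio <- function(ratio, seeds, n_cells = 50, ref_mean = 10,
                                ...) {
  one <- function(mult, s, group) {
    sc <- generate_scene(scene_params(
      n_cells = n_cells, mito_per_cell_mean = ref_mean * mult, n_frames = 1,
      lyso_per_cell_mean = 3, seed = s, ...))
    proj <- render_projection(sc, 1)
    nuclei <- segment_nuclei(proj)
    cells <- segment_cells(proj, nuclei)
    mito <- segment_organelles(proj, cells, "mitochondrion")
    counts <- mito_stats_per_cell(mito, cells)
    data.frame(group = group, seed = s, count = counts$mito_count)
  }
  per_cell <- rbind(
    do.call(rbind, lapply(seeds, function(s) one(1, s, "control"))),
    do.call(rbind, lapply(seeds, function(s) one(ratio, s + 5000, "mutant")))
  )
  pct <- normalize_to_control(per_cell$count, per_cell$group, "control")
  list(pct_of_control = mean(pct[per_cell$group == "mutant"]),
       per_cell = per_cell)
}
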