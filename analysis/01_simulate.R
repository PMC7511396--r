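#!/usr/bin/env Rscript
# Simulate the study's raw materials at desk scale: one basal control-like
# time-lapse scene (written as TIFF + ground truth + parameters) and the
# ATP inhibitor plates for a differentiation series. Everything downstream
# (02-04) re-reads these files, so the whole analysis is reproducible from
# this script's outputs alone.

suppressMessages(library(mitoquant))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# a small control-like field: 12 cells, basal engulfment 0.09, 4 frames
scene <- generate_scene(scene_params(n_cells = 12, mito_per_cell_mean = 15,
                                     n_frames = 4, basal_engulf_prob = 0.09,
                                     seed = 20260901))
write_scene(scene, file.path(out, "scene_control_basal"))
gt <- scene_ground_truth_table(scene)
message(sprintf("scene: %d cells, %d mitochondria, ground-truth fraction %.3f",
                length(scene$cells), nrow(scene$mito),
                mean(gt$fraction, na.rm = TRUE)))

# ATP plates through differentiation (condition means emulate the published
# progression from glycolytic progenitors to OXPHOS-reliant day-27 neurons)
series <- list(
  "0"  = c(untreated = 3.1, oligomycin = 2.9, "2DG" = 0.9),
  "12" = c(untreated = 5.5, oligomycin = 4.3, "2DG" = 2.4),
  "17" = c(untreated = 8.0, oligomycin = 5.5, "2DG" = 4.8),
  "22" = c(untreated = 11.0, oligomycin = 5.0, "2DG" = 8.5),
  "27" = c(untreated = 15.1, oligomycin = 3.5, "2DG" = 8.5)
)
for (day in names(series)) {
  pl <- generate_atp_plate(series[[day]], cv = 0.08, n_wells = 6,
                           seed = 500 + as.integer(day),
                           timepoint = as.integer(day), group = "control")
  write.csv(pl, file.path(out, sprintf("atp_plate_day%s.csv", day)),
            row.names = FALSE)
}
message("wrote ATP plates for days ", paste(names(series), collapse = ", "))
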