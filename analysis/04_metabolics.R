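#!/usr/bin/env Rscript
# ATP partitioning through differentiation from the plates written by
# 01_simulate.R: per-day %OXPHOS / %glycolysis, the metabolic switch day,
# and the control-vs-mutant normalized ATP level.

suppressMessages(library(mitoquant))

out <- "results/metabolics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plates <- Sys.glob("results/simulated/atp_plate_day*.csv")
if (length(plates) == 0)
  stop("no plates found; run analysis/01_simulate.R first")

cfg <- run_config(plates, out)
partitions <- run_metabolics(cfg)
partitions <- partitions[order(partitions$timepoint), ]
sw <- metabolic_switch_timecourse(
  data.frame(day = partitions$timepoint,
             pct_oxphos = partitions$pct_oxphos,
             pct_glycolysis = partitions$pct_glycolysis))
print(sw$table, row.names = FALSE)
message(sprintf("metabolic switch (first day %%OXPHOS > %%glycolysis): day %s",
                sw$switch_day))
message(sprintf("day-27 %%OXPHOS = %.1f (rounds to %d%%)",
                partitions$pct_oxphos[partitions$timepoint == 27],
                round(partitions$pct_oxphos[partitions$timepoint == 27])))

# normalized cellular ATP, day-17-like deficit (mutant mean 0.82x control);
# replicated as 3 rounds x 4 lines per group, one 12-well plate each
ctrl <- lapply(1:12, function(i)
  generate_atp_plate(c(untreated = 10), cv = 0.05, n_wells = 12,
                     seed = 1700 + i, group = "control"))
mut <- lapply(1:12, function(i)
  generate_atp_plate(c(untreated = 8.2), cv = 0.05, n_wells = 12,
                     seed = 1800 + i, group = "PRKN"))
plates <- do.call(rbind, c(ctrl, mut))
norm <- normalize_atp(plates$luminescence, plates$group, "control")
write.csv(norm, file.path(out, "normalized_atp.csv"), row.names = FALSE)
message(sprintf("normalized ATP: control %.1f +/- %.1f, PRKN %.1f +/- %.1f",
                norm$pct_mean[1], norm$pct_sd[1],
                norm$pct_mean[2], norm$pct_sd[2]))
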