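# mitoquant

High-content quantification of mitochondrial morphology, mitophagy and
metabolic partitioning in patient-derived dopaminergic neurons — an open,
tested re-implementation of the image-analysis and plate-assay computations
behind the *PRKN*-mutant neuron phenotype, together with a ground-truthed
synthetic scene generator that makes every stage verifiable without access
to the original images.

## What it computes

*PRKN* (parkin) mutations cause early-onset Parkinson's disease; parkin
works in mitophagy, the autophagic clearance of damaged mitochondria. In
patient-derived neurons the mitophagy defect only appears once the cells
switch from glycolysis to oxidative phosphorylation (OXPHOS) during
differentiation. The quantities behind that finding are:

- **Live mitophagy assay** — on each max-projected time-lapse frame
  (TMRM mitochondria + Lysotracker lysosomes, 18-minute sampling), a
  *mitophagy event* is a mitochondrion whose mask is 100% contained in a
  single lysosome mask; the per-cell fraction
  `m = engulfed mitochondria / mitochondria` is tracked over time under
  basal or inhibitor-induced (antimycin A + oligomycin) conditions.
- **Segmentation** — nuclei (Otsu + watershed), cell regions (seeded
  propagation over a cytoplasm proxy), organelles (top-hat + in-cell Otsu),
  caspase-3 puncta and marker-positive cell fractions.
- **Morphometrics** — per-cell mitochondrial number, size, intensity and
  interconnectivity (mean area/perimeter, µm); cell roundness
  (isoperimetric, circle = 1) and elongation (axis ratio); normalization to
  the control-group mean (percent of control).
- **Metabolic partitioning** — from an ATP luminescence plate with
  untreated / oligomycin / 2-deoxyglucose / both wells, with untreated set
  to 100%:
  `%OXPHOS = 100 (U − O)/U`, `%glycolysis = 100 (U − D)/U`,
  `residual = 100 B/U`, plus the differentiation day at which %OXPHOS first
  exceeds %glycolysis (the metabolic switch).
- **Statistics** — two-way ANOVA (genotype × timepoint) with Sidak or Tukey
  contrasts, and repeated-measures ANOVA across all time points; the unit
  of replication is the differentiation round, not the cell.
- **Synthetic scenes** — `generate_scene()` builds cells, mitochondria,
  lysosomes and per-frame engulfment states with exact ground truth and
  renders noisy 7-plane z-stacks; `generate_atp_plate()` builds
  cv-controlled luminescence plates. Fixed seeds give bit-identical output.

See `vignettes/mitoquant-methods.Rmd` for the model, conventions,
parameter defaults and limitations.

## Worked example

A desk-scale end-to-end run: simulate a control-like field at the day-27
basal mitophagy rate (0.09), run the live assay, and partition an ATP
plate built from the day-27 control condition means.

```r
library(mitoquant)

scene <- generate_scene(scene_params(n_cells = 12, mito_per_cell_mean = 15,
                                     n_frames = 4, basal_engulf_prob = 0.09,
                                     seed = 20260901))
cfg <- run_config(list(scene), out_dir = "demo_run", condition = "basal")
tc <- run_live_mitophagy(cfg)
round(mean(tc$mean_m), 3)
#> [1] 0.093

plate <- generate_atp_plate(c(untreated = 15.1, oligomycin = 3.5,
                              "2DG" = 8.5), cv = 0, n_wells = 6)
atp_partition(plate)
#> ATP partition: %OXPHOS = 76.8, %glycolysis = 43.7, residual(both) = NA (untreated mean 15.1)
```

The measured mean per-cell mitophagy fraction (0.093) recovers the
generator's engulfment probability (0.09) to within its binomial sampling
error, and day-27 control neurons derive 76.8% ≈ 77% of their ATP from
oxidative phosphorylation. `demo_run/` now holds the event, fraction and
time-course CSVs plus the resolved config and log.

The `analysis/` directory stages the full study as numbered drivers —
`01_simulate.R` (scenes + ATP plates), `02_morphology.R` (fragmentation and
number contrast), `03_mitophagy.R` (basal and induced time-courses,
repeated-measures test), `04_metabolics.R` (partition series, switch day,
normalized ATP), `05_group_stats.R` (two-way ANOVA with Sidak contrasts) —
each writing its tables under `results/`.

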