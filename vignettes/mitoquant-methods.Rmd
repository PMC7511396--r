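---
title: "Quantifying mitochondrial morphology, mitophagy and metabolic partitioning with mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial morphology, mitophagy and metabolic partitioning with mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## The problem

Patient-derived dopaminergic neurons carrying *PRKN* mutations show a
mitochondrial phenotype that only emerges once the cells switch from
glycolysis to oxidative phosphorylation during differentiation: fragmented
mitochondria, roughly doubled mitochondrial number, elevated mitochondrial
ROS, reduced membrane potential and ATP, and — centrally — collapsed basal
and induced mitophagy. The quantities behind those statements come from
high-content imaging pipelines (commercial, closed-source) and from
inhibitor-based plate assays. `mitoquant` re-implements that quantification
stack as open, tested code:

1. **Segmentation** of maximum-projection fields into nuclei, cell regions
   (cytoplasm including projections), mitochondria and lysosomes.
2. **Morphometrics**: per-cell mitochondrial number, size, intensity and
   interconnectivity; cell roundness and elongation.
3. **The live mitophagy assay**: a mitophagy event is a mitochondrion whose
   binarized mask is 100% contained in a lysosome mask; per-cell fractions
   are tracked over a time-lapse sampled every 18 minutes, under basal or
   inhibitor-induced (antimycin A + oligomycin) conditions.
4. **Fixed-assay validation**: LC3/Tomm20 colocalization under the same
   containment rule, and total per-cell Tomm20 as an inverse mitophagy
   readout.
5. **Metabolic partitioning**: % of ATP production attributable to OXPHOS
   and to glycolysis from oligomycin / 2-deoxyglucose inhibitor plates.
6. **Group statistics**: two-way ANOVA with Sidak or Tukey contrasts, and
   repeated-measures ANOVA across all time points.

No raw patient images are publicly available, so the package ships a
**synthetic scene generator** that emulates the control and mutant
phenotypes with exact ground truth. Every pipeline stage is validated
against that ground truth, against closed forms, or against brute-force
oracles.

## The mitophagy event rule

For mitochondrion mask $M$ and lysosome labels $L_j$ on the same
max-projection grid, the overlap fraction is

$$\omega(M) = \max_j \frac{|M \cap L_j|}{|M|},$$

and an event is recorded when $\omega \ge \tau$ with $\tau = 1$ by default
(the strict 100% rule). Two design points were genuinely open:

* **Single lysosome vs class union.** Whether containment must be within a
  single lysosome label or the union of all lysosomes is not derivable from
  the assay's published description. We require a *single* label by default — the
  union rule would score a mitochondrion bridging two adjacent lysosomes as
  an event, which contradicts the biology of engulfment — and expose
  `single_lysosome = FALSE` for the union convention.
* **The threshold.** $\tau = 1$ is exact on synthetic renders, but on real
  data single boundary pixels flip with noise; `overlap_threshold` is
  config-exposed for that reason. Lowering $\tau$ can only add events
  (monotonicity is property-tested).

Each frame is scored independently; there is no object tracking. The
reported quantity is a per-time-point cross-sectional fraction
$m = \text{(distinct engulfed mitochondria)}/\text{(mitochondria)}$ per
cell, so tracking would add machinery without changing the estimand. Cells
with zero mitochondria are excluded from $m$, never scored 0.

## The synthetic generator

`generate_scene()` lays out star-convex cells (wobbled, anisotropically
scaled circles) on a jittered grid, places elliptical mitochondria and disk
lysosomes inside each cell, and samples a per-mitochondrion per-frame
engulfment state — Bernoulli with the basal probability, or a per-frame
induced curve. Engulfment is an absorbing state within a frame but
reversible between frames (lysosomal turnover), which keeps the
cross-sectional engulfed fraction equal to the engulfment probability at
every frame; that matches the per-time-point fractions the assay reports,
rather than a cumulative flux. An engulfed mitochondrion is drawn condensed
at its host lysosome's centre, scaled so its mask sits wholly inside the
lysosome with a safety margin (cargo in an autolysosome is being degraded;
the shrinkage also makes the ground truth unambiguous). Each engulfed
mitochondrion gets its own host lysosome within a frame; the per-cell
lysosome count is the maximum of a Poisson draw and the peak simultaneous
demand, which affects only geometry, never the engulfment rate.

Default parameters are the day-27 control conditions: 50 cells per field,
~20 mitochondria per cell, basal engulfment probability 0.09 (mutant-like
scenes use 0.025, induced plateaus 0.3), 10 frames at 18-minute spacing,
7 z planes, 0.3 µm pixels, mitochondria of ~1 µm², lysosomes of 1.2 µm
radius. Object intensities (mitochondria ~3000, lysosomes ~3500, nuclei
4000 over a background of 100, Gaussian read noise SD 40 on a 16-bit
scale) give the high signal-to-noise ratio typical of a confocal
high-content system at these exposure settings. One RNG stream drives
geometry and engulfment; an independent per-frame stream drives noise, so
geometry is bit-stable when only the noise model changes and reruns under a
fixed seed are bit-identical.

Rendering spreads each object's intensity across z with a Gaussian focal
weight equal to 1 at its focal plane, so the per-pixel maximum over z
recovers the in-focus image exactly; noise is applied per plane *before*
the projection, as on a real microscope. Objects are drawn with hard edges
— there is no point-spread-function blur, photobleaching, stage drift or
neurite-graph morphology. That is the main gap between the simulation and
real data: passing recovery tests shows the measurement pipeline is
unbiased on well-resolved objects at realistic SNR, not that it would
survive heavily blurred, clumped or drifting material. Two generator
constraints keep the ground truth well defined: free mitochondria never
overlap lysosome interiors (their centres stay a lysosome radius away), and
objects of the same class keep a 2 px gap so labels never merge. Objects
smaller than 6 px (below any plausible detection limit at 0.3 µm/px) are
not generated at all; the minimum-area filter in segmentation (3 px) is
therefore never the binding constraint on synthetic data.

## Segmentation

All quantification runs on maximum projections, never per z plane.
Thresholds nobody published are chosen by standard neutral methods and
config-exposed rather than claimed to match the commercial software:

* **Nuclei**: Gaussian blur (σ = 1 px), Otsu threshold, minimum area 25 px,
  distance-transform watershed to split touching nuclei.
* **Cells**: seeded propagation (`EBImage::propagate`) from nucleus seeds
  over a cytoplasm proxy — the smoothed sum of the mitochondria and
  lysosome channels — masked at median + 6·MAD of the proxy (Otsu
  optional). The MAD rule is the default because the proxy histogram has
  three modes (background, cytoplasmic haze, organelles) and Otsu can land
  between haze and organelles, truncating the cell body.
* **Organelles**: white top-hat (disc radius 9 px) to remove the
  cytoplasmic haze, Otsu on the in-cell histogram, minimum area 3 px,
  labels split at cell boundaries so no organelle spans two cells.
* **Spots / markers**: smoothed local maxima above median + k·MAD of the
  non-cell background (k = 8) for puncta; a cell is marker-positive when
  its mean intensity exceeds k× the background median (k = 3).

Cells touching the field border are flagged and excluded from per-cell
statistics by default — truncated morphology biases roundness and
elongation. Pixel coordinates are 0-based row-major; areas are reported in
µm² via `pixel_size²`.

## Morphometrics conventions

* **Interconnectivity** is the mean over a cell's mitochondria of
  area/perimeter in µm, the convention of the widely used ImageJ
  mitochondrial-morphology macro; commercial high-content software reports it
  without a published definition, so printed magnitudes (0.07 vs 0.04) are not comparable
  across software and are deliberately not targeted. The property that *is*
  asserted: fragmenting a fixed total area into $k$ circles scales it as
  $1/\sqrt{k}$, and any straight-cut split lowers it.
* **Perimeter** uses the Cauchy–Crofton 4-direction estimate, which has
  much lower rasterization bias than boundary-pixel counting: a rasterized
  disk scores roundness 1.00 to three figures.
* **Roundness** is the isoperimetric ratio $P^2/(4\pi A)$ (circle = 1,
  *higher = less circular*); **elongation** is the second-moment major/minor
  axis ratio (circle = 1). The published convention scores rounder cells
  *higher* and elongation on an undefined scale ~0.01; both its roundness
  and elongation formulas are unpublished, so those printed values cannot
  be reproduced and are not targets. `roundness_higher_is = "round"`
  reports the reciprocal for readers who want the published direction.

## Metabolic partitioning

With condition means $U$ (untreated), $O$ (oligomycin), $D$
(2-deoxyglucose), $B$ (both), untreated set to 100%:

$$\%\mathrm{OXPHOS} = 100\,\frac{U - O}{U},\qquad
  \%\mathrm{glycolysis} = 100\,\frac{U - D}{U},\qquad
  \mathrm{residual} = 100\,\frac{B}{U}.$$

Condition means are arithmetic means of wells with no outlier rejection
(the assay protocol specifies none); a robust-median option exists but
is off by default. Negative inhibition is reported as a negative percentage
with a warning, never clipped — it is diagnostic of a failed treatment.
The three percentages need not sum to 100 and are never rescaled; a
deviation beyond 10 points is flagged. The worked example from the printed
day-27 control means (15.1, 3.5, 8.5) gives
$100(15.1-3.5)/15.1 = 76.8 \to 77\%$ OXPHOS-dependence. From the printed
progenitor means (3.1, 2.9, 0.9) the formulas give 71.0% / 6.5%, slightly
off the printed 70.4% / 3.4% — the headline percentages reported alongside
those means were evidently computed from unrounded values, so only the 77% figure (stable under
rounding) is used as a check. The switch day is the first timepoint at
which %OXPHOS exceeds %glycolysis.

## Statistics

The unit of replication is the differentiation round (n = 3–4 per line),
never the individual cell: cells are averaged per round before testing, to
match the reported n and avoid pseudoreplication. `two_way_anova()` is the
standard fixed-effects decomposition with genotype contrasts per timepoint;
Sidak adjustment is $1-(1-p)^k$ over the $k$ reported contrasts, Tukey uses
the studentized range (reported analyses alternate between the two without a
stated rule, so the correction is a per-run choice).
`repeated_measures_anova()` tests the genotype main effect in the
between-subject stratum of a genotype × time design with subject nested in
genotype — the "repeated measures across all time points" comparison used
for mitophagy time-courses. Both are `stats::aov` fits; the two-way F
statistics are property-tested against a hand-written sums-of-squares
oracle at 1e-8.

## Problem sizes and numerical choices

Recovery experiments run at the study's conditions scaled to a desk: 3
replicate scenes of 50 cells × ~20 mitochondria × 10 frames for basal
recovery (30,000 Bernoulli observations per rate, binomial SE ≈ 0.0017 at
rate 0.09), 6 frames with induction at frame 3 for the induced plateau, 50
cells × 3 seeds per group for count normalization, and — following the
study's replication design of three differentiation rounds across four
lines per group — 12 replicate 12-well plates (CV 0.05) per group for ATP
normalization. Unit tests use 6–12-cell scenes. Recovery is asserted within
2 binomial SE of the generator rate — the estimator's own sampling error,
not a tuned tolerance. The plate replication matters: a *single* 12-well
plate pair at CV 0.05 leaves the normalized ATP estimate with an SD of
about 1.7 percentage points, so group contrasts at that plate size are only
interpretable across replicate rounds, exactly as the assay is used.

Degenerate inputs are defined behaviour throughout: blank images give empty
label maps, not errors; zero segmented cells is an error distinct from 0%
marker positivity; cells with zero mitochondria are excluded with a log
message; missing inhibitor conditions give missing partition fields, not
zeros; a plate without untreated wells, or an untreated mean ≤ 0, is an
error. Saturation at the 16-bit ceiling clips with a warning. Ties in the
single-lysosome overlap maximum are broken toward the first label — with a
containment threshold of 1 the tie can only occur between identical full
covers, where the choice does not affect the event count.

## Limitations

* The generator's cells are convex-ish blobs; real day-27 neurons have
  processes much longer than the soma. Segmentation of projections is
  exercised only as far as the cytoplasm proxy reaches.
* No PSF, bleaching, drift or z-aliasing: recovery results bound pipeline
  bias, not microscope physics.
* Printed values tied to unpublished formulas (interconnectivity scale,
  roundness/elongation magnitudes) or to real cultures (marker
  percentages, survival, caspase-3 rates) are reproduced only as
  generator-recovery demonstrations, not as claims about biology.
* The 0.09/0.025/0.3 mitophagy levels are treated as fractions on the same
  scale the pipeline reports; the source is ambiguous between fraction and
  percentage, and recovery tests are scale-consistent under either
  reading.
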