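---
title: "Models and methods behind secscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secscreen)
```

# The assay and the statistic

`secscreen` analyzes image-based siRNA double-knockdown secretion screens
performed on spotted chambers. Cells grow over a grid of siRNA spots
(384 per chamber in the default design) after being reverse-transfected in
suspension with a chamber-wide *background* siRNA — a non-targeting
control, or siRNA against one of the paralogous COPII inner-coat subunits
SEC23A/SEC23B. A temperature-synchronized VSVG reporter is released from
the ER; after fixation, a surface-only antibody stain (A647) and the total
reporter fluorescence (YFP) are imaged per cell.

**Per-cell transport ratio.** For each segmented cell,

$$r = \frac{\text{surface marker intensity}}{\text{total marker intensity}},$$

the fraction of reporter delivered to the plasma membrane. Intensities are
background-corrected sums over the cell region; cells with non-positive
total intensity are flagged and excluded.

**Transport score.** Per-cell ratios average to a spot statistic $x_i$
(mean over cells, with a minimum-cell guard). To compare replicates and
remove spatial plate effects, each spot is normalized against its local
neighborhood:

$$\mathrm{score}_i = \frac{x_i - X_i}{\mathrm{MAD}_i},$$

where $X_i$ is the median of the $5\times5$ window of spot ratios centered
on spot $i$ (center included, 25 values on a full plate) and
$\mathrm{MAD}_i$ is the median absolute deviation of the same window,
used *without* the 1.4826 consistency constant. Negative scores mean
transport inhibition; positive scores acceleration.

Window conventions worth making explicit:

* **Center inclusion.** The window includes the spot itself, so the median
  is computed over 25 values on a full plate. A strong center spot shifts
  its own reference only marginally (one rank of 25), and this matches the
  printed count of values.
* **Edges.** Windows truncate at plate edges rather than mirroring
  (mirroring fabricates data). Spots whose window retains fewer than
  `min_window = 12` usable values are flagged `insufficient_window` and
  carry no score — on a full 16×24 plate this affects only the four
  corners (9-value windows).
* **Degenerate windows.** A window with zero MAD cannot be scored; the
  spot is flagged `degenerate_mad`, never scored infinite.
* **Control spots in windows.** `score_plate()` includes control spots in
  windows by default (the median tolerates sparse outliers). The screen
  pipeline (`analyze_screen()`) excludes them: control spots carry
  engineered effects that *differ between backgrounds* (siSEC23B is
  neutral on a control chamber but strongly inhibited on a SEC23A
  chamber), and letting them into windows makes local MADs systematically
  larger on background chambers, attenuating double-knockdown scores by
  tens of percent relative to singles. Excluding controls keeps the score
  scale shared across chambers, which the synergy test depends on.

# Plate QC, replicates, and hit calling

A plate passes QC when its positive controls (COPI-coat siRNAs) show
strong inhibition — median positive-control score at most `pos_max = -1.5`
— and its negative controls sit close to zero. For the negative criterion
the default compares the *median* of the negative-control scores against
`neg_abs_max = 0.5`; a per-spot "all within the band" mode is available.
The median rule is deliberate: an individual null spot's score carries a
persistent layout-induced offset with standard deviation around 0.4 score
units (the window median is itself an estimate from 24 neighbors), so a
per-spot rule rejects many genuinely sound plates. For the same reason the
default chamber design carries 12 negative spots (6 Scramble, 6 Neg9)
scattered on a coarse interior lattice; with a dozen positions the
chamber-level negative median reflects plate quality rather than layout
luck. When a multinucleation fraction from the INCENP transfection-QC
spots is supplied, it must reach `min_transfection = 0.5`; when it is not
measured, the criterion is recorded as not assessed.

Conditions — (siRNA, background) pairs — require at least three biological
replicates; their score is the median over replicates (duplicate spots of
a condition within one plate are collapsed to their median first).

**Synergy rule.** For each sample siRNA $g$ and background $b$:

$$\Delta_{g,b} = \mathrm{double}_{g,b} -
  (\mathrm{single}_g + \mathrm{single}_b),$$

with the singles measured on control-background chambers (the background's
own single score comes from the siSEC23A/siSEC23B spots spotted on every
chamber). A pair is a hit when the double score is a strong effector
(score $\le -1.5$, or $\ge +1.5$ for accelerators) *and*
$|\Delta_{g,b}| > 1$ transport-score unit. The absolute-value form
captures both synergy and buffering; a signed mode restricted to
deviations in the double's own direction is available. Hits rank by
|double score|, ties by $|\Delta|$, then gene id.

# The synthetic screen generator

`screen_truth()` + `simulate_plate()` generate per-cell ratio tables with
known ground truth. The generative model is additive on the ratio scale:

$$r_{\text{cell}} = \max\!\big(0,\; \beta_0 + \alpha_g + \alpha_b +
  \gamma_{g,b} + G(\text{row}, \text{col}) + \varepsilon\big),
  \qquad \varepsilon \sim N(0, \sigma)$$

with defaults chosen to emulate the screen's conditions:

| parameter | default | rationale |
|---|---|---|
| base ratio $\beta_0$ | 0.5 | mid-scale reporter delivery after 1 h release |
| per-cell noise $\sigma$ | 0.15 ratio units | 30% CV per cell, typical for per-cell intensity ratios |
| cells per spot | Poisson(200) | a confluent 384-spot chamber field |
| plate gradient $G$ | low-order random polynomial, amplitude 20% of $\beta_0$ | smooth edge/center effects the windowed score must remove |
| library main effects $\alpha_g$ | $N(0, 0.08)$ | a targeted regulator library has broad true-effect spread; the windowed MAD presupposes neighbor diversity |
| COPI positive controls | $-0.3$ | strong inhibition (≈60% of base) |
| SEC23A/B singles and backgrounds | 0 | screen conditions are titrated so either single knockdown alone has no transport phenotype |
| SEC23A×SEC23B co-depletion | $-0.3$ | the paralog pair is the built-in strong positive interaction |
| planted synergistic pairs | interaction $-0.25$, singles within $\pm0.05$ | clearly non-additive pairs with unremarkable singles |

Everything is deterministic given the truth object and a seed, and
`write_truth()`/`read_truth()` round-trip the truth losslessly next to
every simulated dataset.

What the generator does *not* emulate: segmentation errors and debris,
per-spot technical variation in transfection efficiency, intensity
vignetting, cell-density effects on transport, or cross-contamination
between neighboring spots. Passing recovery tests therefore demonstrates
the correctness and calibration of the *statistical pipeline* under its
own model, not robustness to every failure mode of real screen images.

**Calibration caveats the simulations make visible.** The transport score
is self-normalized: under an exchangeable null (no spatial structure, all
spots alike) the score behaves like $Z/0.674$, so |scores| near 1 are
expected on an effect-free plate no matter how small the noise — the
statistic measures deviation *relative to local spread*, and only plates
with real neighbor diversity (or strong gradients) produce small null
scores. Likewise the window MAD is estimated from at most 25 values and
carries roughly 18% relative error; since it divides the score, strong
effectors inherit a proportional noise term, and their double-vs-single
additivity differences fluctuate by several tenths of a score unit even
with five replicates. Both behaviors are quantified by the package's
acceptance script on simulated plates; they are properties of the
published statistic, not implementation artifacts.

# Imaging pipelines

**2D fields (`image_quant`).** Nuclei: Gaussian smoothing, Otsu global
threshold, hole filling, distance-transform watershed to split touching
nuclei, minimum-size filter (15 px), contiguous relabeling. Cells: seeded
region growing on the total-marker intensity landscape from nucleus seeds
(the CellProfiler secondary-object strategy), partitioning the Otsu
foreground; `merge_seed_distance` optionally merges adjacent nuclei into
one seed so binucleated cells (INCENP knockdown) come out as single cells
for the multinucleation readout. Background correction subtracts the
image's 5th-percentile intensity, clipped at zero — a flat-background
estimate appropriate for the simulators' additive baseline. Expression
binning is left-closed/right-open at configurable thresholds (data-driven
33rd/66th percentiles by default). The RUSH transport index subtracts the
mean non-release (leak) ratio from the mean release ratio, floored at 0;
the assay design provides no per-cell pairing, so the correction is at the
condition level.

**3D puncta (`spot3d`).** Two cube median filters (radius 1 for noise,
radius 4 for local background, z-radii rescaled by the recorded voxel
anisotropy), subtraction, clipping. Seeds are local maxima in a 3×3×3
neighborhood above a threshold; median filtering flattens peaks into small
plateaus, so plateau ties yield a single seed (lowest linear index).
Segmentation floods from seeds in order of decreasing intensity
(seeded watershed), splitting touching structures along intensity valleys;
the default foreground threshold is half the seed threshold. Large bright
regions (above the same threshold, 6-connected, volume ≥ 300 voxels by
default) are treated as Golgi-like clusters: segmented separately,
excluded from spot counts and intensities *before* per-cell statistics.
Spots attach to cells by centroid containment; condition summaries refuse
to report below 100 quantified cells.

**Focal adhesions (`adhesion_quant`).** The ventral plane is the slice
maximizing normalized variance $\sigma^2/\mu$ (ties to the lowest index;
an all-zero stack is flagged). Segmentation thresholds (Otsu by default,
hence invariant to intensity scaling) the maximum projection of the three
slices centered on that plane, clamped at stack edges, and drops regions
under 5 px. Totals, counts, mean sizes and intensities normalize per cell
by the nucleus count; summaries refuse below 50 cells. Whether per-cell
metrics should instead use full cell-boundary segmentation is left open;
nucleus-count normalization is the default and both masks are accepted.

# Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data built
at run time: screens of 4 chambers × 384 spots × 3 backgrounds × 5
replicates (~0.9M simulated cells per screen, ten screens), 48×48×16-voxel
puncta stacks, 64×64×9 adhesion stacks, and 96–160 px cell fields — sizes
at which every stage completes in seconds while leaving the statistics
well within their asymptotic regimes. Grid coordinates are 0-based
row-major everywhere (files included); z-indices are 1-based, following R
array indexing. All tie-breaks are deterministic (lowest index / first
occurrence), so identical configs and seeds reproduce outputs
byte-for-byte.

# Known limitations

* The scoring model assumes the 5×5 neighborhood is representative of the
  spot's null; clustered strong effectors (e.g. a gene family spotted
  together) would bias their own reference windows.
* The additivity test inherits the score's local scale; conclusions about
  weak interactions (<1 score unit) are below its resolution, and strong
  single effectors accumulate multiplicative MAD noise (see calibration
  caveats above).
* Segmentation modules are classical (threshold/watershed); they are
  appropriate for the well-separated synthetic objects and for
  high-contrast stains, not for dense tissue or low-SNR live imaging.
* The RUSH correction treats leak as condition-constant; heterogeneous
  per-cell leak shifts the index by the difference in means only.
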