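---
title: "Quantifying paralog-deletion protein redistribution: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paralog-deletion protein redistribution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paralogshift` analyses reciprocal paralog-deletion imaging screens: for
every pair of paralogous proteins (A, B), four strains are imaged — A-GFP
and B-GFP, each in the wild-type and in the partner-deletion background —
and the package quantifies whether each protein's subcellular distribution
responds to the loss of its partner. This vignette explains the models
behind each stage, the parameters that matter, and the design choices made
where the design was genuinely open.

## The screen model and its synthetic emulation

The generator is not a fixture factory but a model of the screen itself.
Its defaults mirror a realistic acquisition design: three replicates, four
fields per condition, and 50–100 cells per field, so a condition contributes
600–1,200 cells. Cells are non-overlapping ellipses (semi-major axis 12–15
px at the default 448×448 field) with a configurable fraction (default
0.15) placed in touching clumps to exercise instance splitting.

Compartment templates are parametric geometry — a cytoplasmic fill, a
nuclear inner disk, an ER annulus, an offset vacuole disk, and scattered
punctae — rather than learned textures, because analytic templates give
exact expectations: each template is normalized to mean 1 over the cell, so
the mean fluorescence over a stencil equals the cell's abundance parameter
by construction, and planted relocalization (mixing fraction *f* of a target
template) leaves mean abundance unchanged. Noise is Poisson shot noise plus
Gaussian readout noise over a constant background offset (default offset 40,
read-out SD 2 at gain 1), the standard first-order model of fluorescence
statistics. Background level and noise magnitudes for the original
microscope are not published; these defaults were fixed once at values that
make the signal-to-noise comparable to a bright fluorescence channel and
were not revisited.

Planted effects define the ground truth downstream stages must recover: a
multiplicative abundance factor (default 2), a relocalization fraction
(default 0.6), with effect pairs cycling through abundance-only,
relocalization-only and combined scenarios. Controls are random pairings
with no effect. What the generator deliberately does **not** model:
photorealistic yeast texture, bud morphology, multichannel crosstalk, or
focus drift. Passing tests therefore demonstrate that the algorithms recover
known effects under idealized optics — not that they are robust to every
artifact of real screens.

## Segmentation

Instance masks are encoded into soft targets: each stencil is eroded with
the minimal cross (a pixel survives only if all four neighbours share its
label — this is what separates touching cells), the Euclidean distance to
background is computed on the eroded map, clipped at 20 px and divided by
the clip, and the target is `0.8 * binary + 0.2 * scaled distance`. Border
pixels sit near 0.8 and centers at 1, focusing the model on object centers.
Two conventions the definition leaves open: the distance is divided by the
clip value so the maximum is exactly 1, and out-of-image neighbours count as
same-label during erosion so border cells are not eaten away.

The cell-probability model is a deliberately small, fully trainable pixel
classifier: a one-hidden-layer network over multiscale Gaussian features
(raw intensity, blurs at sigma 1–8, gradient magnitude, a
difference-of-Gaussians band), trained with binary cross-entropy, minibatch
SGD with momentum, random crops with flips and intensity scale/shift
augmentation in [0.5, 2) and [−1, 1), and a cosine-annealed learning rate.
This honors the training contract of a full encoder–decoder segmentation
network at a size that trains in seconds on a laptop; on the synthetic
fixture it reaches pixelwise AUC > 0.99 against ground truth. Inference
pads inputs by reflection to dimension divisible by 32 and crops the output
back, so models and images of any size compose.

Instances come from a seeded watershed implemented as a priority flood in
compiled code: 4-connected components of probability ≥ 0.8 seed the flood,
which descends the probability surface restricted to the ≥ 0.5 foreground.
Boundary-threshold foreground unreachable from any seed is discarded — the
alternative (keeping unseeded foreground as extra objects) would admit
low-confidence debris. Objects outside [256, 8192] px are removed; the
generator's cell sizes (areas ≈ 360–700 px) sit comfortably inside this
window, which is the point: the size filter rejects debris and merged
clumps, not real cells.

## Embedding and the redistribution score

Each detected cell contributes a 64×64 frame cut from the normalized image
around its centroid (reflection-padded near borders; border handling at the
screen stage is not otherwise specified, and padding keeps the cell-count
bookkeeping simple). Raw background-subtracted frames are kept separately
for abundance, which is defined on raw intensities.

Two embedding backends sit behind one interface:

* **Deterministic handcrafted backend** (default for validation): five
  feature blocks, each rotated by an orthonormal DCT and placed in disjoint
  coordinate ranges of the 128-d output. The intensity-summary block holds
  the frame mean plus background-referenced contrast quantiles: contrasts
  are anchored at the frame minimum (background-subtracted images carry an
  exact zero atom from clipping) and scaled by the lower quartile of the
  positive background residuals, two anchors that are fixed in raw
  log-intensity units — this cancels the per-image affine normalization, so
  a protein's brightness is measured on a comparable scale across images
  and a planted abundance change separates cleanly from image-to-image
  normalization jitter. The four shape blocks (radial mean and SD profiles,
  intensity histogram, gradient-magnitude quantiles) are computed on the
  per-frame standardized central disk (radius 20 px), which excludes
  neighboring cells in crowded fields and is exactly invariant to affine
  intensity changes. The construction involves no training and no
  randomness, so screens embed bit-reproducibly, and a constant intensity
  shift moves only the summary block, which makes the backend's behavior
  analyzable in tests.
* **Trained classifier backend**: a protein classifier (penultimate layer
  width 128) trained on wild-type-background frames only, with categorical
  cross-entropy, flip augmentation, cosine-annealed SGD, and field 4 held
  out for validation. Inputs are 4×4 mean-pooled, standardized frames. It
  reaches > 0.9 held-out accuracy on two-class synthetic fixtures within a
  few epochs.

The redistribution score is the Euclidean distance between a protein's
128-d condition centroids (cells pooled across replicates — replicate-level
weighting is not used; with unequal replicate sizes pooling weights cells
equally, which matches the per-cell statistical unit used everywhere else).
No feature scaling is applied before the distance; Z-scoring is reserved for
the PCA visualization, which exists only to display a pair's four
conditions and draws the wild-type-to-deletion centroid arrows (principal
component signs are fixed by making the largest-magnitude loading positive,
so reruns are identical).

The classification threshold is selected by ROC analysis against
negative-control proteins: candidate cuts are midpoints between consecutive
sorted unique pooled scores; among candidates minimizing the false positive
rate, ties are broken by maximal true positive rate and then by the smaller
threshold. Midpoints avoid the boundary ambiguity of "greater than" on
observed values. The tie-break is a package choice and is recorded in the
returned object. The original screen's printed cut (4.73) is kept as a
fixed annotation constant and never recomputed from synthetic data, whose
embedding scale is different.

## Abundance statistics

The abundance score of a condition is the grand mean raw pixel intensity
over all frames (pixel-weighted). The change is
`log2(score_del + 1) − log2(score_wt + 1)`; the pseudocount stabilizes dim
proteins, and the generator's default wild-type abundance (≈ 400 a.u.)
keeps scores far enough above 1 that the pseudocount bias on a planted
2× effect stays within the recovery band. Significance is a two-sided
Mann-Whitney U test on per-cell mean intensities pooled across replicates —
the statistical unit is the cell; image- or replicate-level units would
trade power for robustness to field effects, and the per-cell choice
matches the screen's single-cell resolution. P-values are BH-corrected
across proteins, and classes require both |log2FC| ≥ 0.2 and q < 0.05. The
q-gate (rather than the raw p) defines the classes because the adjusted
value is what controls the screen-wide error rate.

## Calls, pairs, and screen summaries

Relocalization annotations are an explicit input (visual inspection in a
real screen, generator truth in tests): the package does not infer
relocalization destinations from embeddings, because the redistribution
score is deliberately non-directional. Calls follow fixed rules:
relocalization into the paralog's wild-type compartment is compensation;
into a compartment foreign to both is dependency; an annotation whose
destination equals the protein's own compartment is invalid. Abundance
increase marks compensation and decrease dependency. Pair summaries count
reciprocal vs single-responder pairs with exact conservation
(`2·reciprocal + single = flagged proteins`), and screen summaries report
integer percentages rounded half-up, matching the reporting convention of
screen literature. Proteins flagged by score but neither relocalized nor
abundance-changed are reported as flag-only rather than forced into a
class.

## Network association

Shared-interactor counts bin pairs at the cohort median; counts exactly at
the median go to `low` and are flagged in an `at_median` column, since a
"fewer or more than the median" rule leaves equality unassigned. Genetic
interaction subsets use the published ε/p thresholds (lenient p < 0.05;
intermediate adds |ε| > 0.08; stringent ε > 0.16 or ε < −0.12;
synthetic-lethal ε < −0.35) and nest by construction. Colocalization uses
the Jaccard index on compartment sets with an inclusive 50 cut.
Localization sources are unioned when they disagree; no precedence rule is
imposed. Enrichment uses the sample odds ratio with Fisher's exact test;
group score comparisons use the two-sided Mann-Whitney U test. Raw BioGRID
parsing is out of scope — the module consumes normalized edge tables, with
the high-throughput filter expressed as a field plus an optional study
whitelist.

## Compartment quantification (two-channel validation)

Segmentation runs on the GFP channel; the marker channel classifies in-cell
pixels: ER at or above the 0.975 intensity quantile, cytoplasm strictly
below the 0.973 quantile, with the (0.973, 0.975) sliver left unassigned —
the gap is preserved verbatim rather than "fixed". Quantiles use the linear
interpolation convention. Cells under 200 px (quantiles unreliable) or with
fewer than 100 ER pixels are discarded with a recorded reason. Edge cells
are removed within a band equal to the median major-axis length. Background
QC discards images outside mean ± k·SD of their replicate's backgrounds
(k = 1 by default, exposed as a parameter since only "mean +/− stdev" is
specified). The image background intensity is defined here as the median
over non-cell pixels, logged per image — the quantity is otherwise
undefined for this pipeline. Per-cell abundances are medians over the
background, which makes them invariant to common intensity scaling.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based (row, col); masks use 0 = background and
  consecutive positive labels; connectivity is 4 for erosion, components
  and the watershed flood (the "minimal cross" convention), 8 for hole
  detection in the Euler number.
* Moment-based shape descriptors add the 1/12 px digitization variance, so
  eccentricity stays strictly below 1 even for single-pixel-wide stencils.
* Constant images (σ = 0 after log transform) are excluded from
  normalization with a warning and recorded in the QC table.
* The watershed priority queue breaks probability ties by insertion order,
  making instance maps bit-reproducible.
* Empty masks, empty score sets, empty rosters, zero-margin contingency
  tables and sub-minimum cell groups all return explicit errors or flagged
  missing values rather than silent numbers.

## Problem sizes used in validation

The package's own validation runs at desk scale, chosen so the full suite
completes in minutes: the recovery fixture uses 6 effect pairs + 2 control
pairs × 4 strains × 3 replicates × 4 fields at ~50–100 cells per field
(≈ 28,000 cells), the trained segmenter uses 6 annotated images, and the
two-channel fixture uses 60 cells per strain over 3 replicates. At these
sizes the pipeline recovers planted effects with zero control false
positives, ≥ 0.85 sensitivity, and log2 fold changes within ±0.2 of the
planted 2× effect; the corresponding acceptance checks rerun these numbers
from scratch.

## Known limitations

* The deterministic embedding is not a learned representation; it is
  sensitive to the radial layout of signal and will underweight phenotypes
  that only a trained texture model would separate.
* The desk-scale pixel classifier assumes roughly convex, bright-on-dark
  cells; it is not a general segmenter for crowded or low-contrast images.
* Synthetic screens have uniform illumination apart from the planted
  offset, so the background-reference stage is exercised under milder
  conditions than a real microscope would present.
* Relocalization destination inference is intentionally out of scope; calls
  require an annotation table.
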