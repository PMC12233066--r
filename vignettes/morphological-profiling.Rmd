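---
title: "Morphological profiling of confluent muscle-cell cultures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphocell)
```

# The model

A condition (cell line × drug × dose) is characterized not by any single
cell but by the *distribution* of shapes in its population. The pipeline
reduces that distribution to a 12-value **morphological profile**: the
mean and sample SD of six per-cell descriptors (area, perimeter, length,
width, length-to-width ratio, compactness) over a bootstrap sample of
200 cells drawn with replacement from the pooled cells of triplicate
wells. Ten such samples are drawn per condition, so replicate profiles
carry the sampling variability of the population statistic itself.

The core assumptions, in order of importance:

* **Population sufficiency.** Merged neighbors, partial cells and other
  instance-level errors are tolerable because profiles average over
  hundreds of cells; the method does not attempt single-cell fidelity.
  Consistent with that, the segmenter never splits touching cells (no
  watershed) — a deliberate simplification whose cost is documented
  below.
* **Descriptor adequacy.** Six geometric descriptors (no texture or
  intensity features) capture the differentiation-relevant phenotype:
  elongation for myotube formation, width for myotube maturity,
  SD features for population heterogeneity.
* **Exchangeability within a condition.** Cells from triplicate wells
  are pooled once before resampling; wells are quality gates (min 200,
  max 5000 cells), not strata. A stratified bootstrap is available
  behind `profiling_config(stratify_by_well = TRUE)` for designs with
  strong well effects.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| bootstrap sample size `n` | 200 | cells | enough for stable means and SDs; matches the protocol's minimum cells per well |
| bootstrap replicates `B` | 10 | — | replicate profiles per condition for clustering/PCA |
| well gates | 200–5000 | cells | under-grown wells rejected; over-dense wells subsampled (seeded) |
| classifier design | 6 × 50 × 1000 | categories × datasets × cells | the published training design; class balance is exact by construction |
| forest | 500 trees, mtry 3 | — | standard defaults at 300 × 12 scale |
| calibration | 2.0 | µm/px | 4 mm² field over 1000² px |
| background kernel | 201 | px | much larger than a cell, smaller than the illumination scale |
| texture window | 9 | px | local-SD support ≈ half a cell width at 4× |
| min object area | 100 | px | ~400 µm² at 2 µm/px, below any real myoblast |
| closing radius | 2 | px | bridges 1–2 px gaps in detected outlines |

None of the segmentation defaults is load-bearing for the tests: every
test pins its configuration explicitly.

# Descriptor conventions

The upstream protocol names its descriptors but defers their formulas to
supplementary material that is not available here, so this package fixes
and documents its own conventions:

* **length/width** — long and short side of the minimum-area oriented
  bounding rectangle, computed by rotating calipers on the convex hull
  of the *smoothed boundary polygon* (see below). Robust for bent,
  elongated cells; length of a bent cell is its chord, not its arc.
* **compactness** — `4πA/P²`, normalized so a disk scores 1; clipped to
  (0, 1] (clip events essentially occur only for few-pixel regions).
* **perimeter** — length of the marching-squares 0.5-isocontour after a
  7-point circular moving-average smoothing of its vertices. Raw
  marching squares overestimates a rasterized disk's perimeter by ~6%
  (staircase); the smoothed estimator measures the disk at +0.1% and an
  axis-aligned 100 × 10 rectangle at −2.4%, and it is what keeps the
  compactness of a disk at ~0.997 and a 10:1 rectangle at ~0.273. A
  4-direction Crofton estimator is available
  (`perimeter_method = "crofton"`); it is excellent for smooth convex
  shapes but biased low (−5.7%) for axis-aligned rectangles, which
  distorts compactness upward — hence not the default.

Smoothing the boundary before the bounding-box step also removes the
rasterization jags that would otherwise inflate the measured width of a
rotated shape by up to 15%; with it, a 100 × 10 rectangle rotated 37°
reproduces the axis-aligned descriptors within 2%.

# The synthetic world

The generator emulates what the segmentation steps exist to remove or
exploit, and nothing more:

* elongated capsules (rectangles with semicircular caps), optionally
  bowed along a circular arc — myotube-like silhouettes with analytic
  ground truth;
* dark bodies with **interior speckle texture** (`texture_strength`,
  default SD 12 gray levels). Real phase-contrast cell interiors are
  textured — this is precisely why the pipeline has a
  texture-enhancement step. With optically blank interiors a local-SD
  map responds only at edges and *no* threshold recovers solid cells, so
  interior texture is part of the stated world, not a convenience;
* a bright halo rim, a low-order polynomial illumination gradient, and
  i.i.d. Gaussian sensor noise;
* placement by rejection sampling with two rules: non-touching cells
  keep `min_gap_px` clearance, and (when `frame_band_px > 0`) no cell
  may *hover* a few pixels from the frame — it either overhangs it or
  keeps clear. The second rule exists because windowed texture detection
  has ~(window/2 + closing radius) pixels of spatial support, so a cell
  1–5 px from the frame attaches to it unpredictably, which would make
  the border-removal count oracle ill-posed rather than test anything.

What the generator does **not** model: phase-contrast optics (no PSF),
fluorescence, time-lapse, cell-to-cell intensity variation, debris.
A green segmentation benchmark therefore establishes that the seven
steps compose correctly against geometric ground truth under realistic
nuisance amplitudes — not that the pipeline would reach the same scores
on micrographs of a real confluent culture, where touching cells are
common. With touching cells admitted (`overlap_fraction > 0`) merged
instances are unmatchable by construction and object-level F1 degrades
accordingly; the population statistics are the part of the method
designed to survive that.

The benchmark fixture (`benchmark_spec()`) is pinned at 1 µm/px with
16 ± 4 µm cell widths. At the acquisition-realistic 2 µm/px an 8-px-wide
myotube loses IoU-0.5 matching to the ~2 px detection spill inherent in
any windowed texture detector; the binarization-stage oracle similarly
uses wide (28 µm) myotubes and a 3-px window, because foreground IoU is
bounded near `A / (A + P·w/2)` for window `w`.

# Numerical choices and degenerate inputs

* **Otsu fallback.** A constant image has no threshold; binarization
  returns an all-background mask with a warning instead of erroring,
  so a blank well degrades to "no cells".
* **Closing at the frame.** The erosion half of the morphological
  closing treats out-of-image pixels as foreground. With the usual
  all-background padding, closing erodes `closing_radius_px` pixels off
  the frame and detaches frame-touching cells, which then survive the
  border-removal step as crescent artifacts.
* **Sample SD** uses the n−1 denominator (unbiased estimator; the
  protocol is silent).
* **Bootstrap determinism.** Every stochastic stage derives its seed
  from the global seed via a fixed integer recurrence (< 2³¹), so one
  seed reproduces the whole run bit-identically while stages remain
  independently reseedable.
* **PCA sign convention.** Each component is flipped so its
  largest-magnitude loading is positive; scores, loadings and explained
  variance ratios are then fully deterministic.
* **Tie-breaks.** Otsu takes the lowest maximizing bin; the forest takes
  the first encountered best split and the lowest class index on vote
  ties; UPGMA inherits `hclust`'s index-order tie-breaking.
* **1-px regions** get width floored at 1 px (and length at least the
  width) with a warning.

# Cross-validation design

The upstream description names both "leave-category-out" and
"leave-and-condition-out" cross-validation. Leaving out an entire
*class* is incoherent for a classifier (the held-out class can never be
predicted), so this package reads the intent as *grouped* CV: all
bootstrap datasets built from the same source experiment are held out
together, preventing any cell from informing both sides of a split. The
grouping key is configurable (`cv_grouping`: experiment, well, or
pseudo-groups over bootstrap replicates for data without provenance —
the last is leakage-prone and only a fallback). A class confined to a
single group is refused with an explanatory error rather than silently
leaking. Both hard votes and vote fractions are reported, since the
upstream confusion-matrix convention is unspecified.

Multicollinearity among the 12 features (means and SDs of related
geometric quantities are strongly correlated) is handled by choice of
method, not by pruning: PCA, correlation distance, and random forests
are all rank-respecting. Impurity importance *divides* credit among
correlated features — the test suite demonstrates this by duplicating a
feature column and checking that the pair's combined importance matches
the original column's (this probe requires `mtry = 12`; at smaller
`mtry` duplication also increases the pair's sampling exposure, which
is a selection artifact, not importance splitting).

# Known limitations

* No declumping: at true confluency the instance-level scores are
  honest only about the population statistic, not per-cell geometry.
* Bent cells report chord length, so extreme curvature compresses the
  length scale.
* The classifier's headline accuracy on the original biological images
  cannot be reproduced without those images; the package's claim is
  that the *machinery* (profile construction, grouped CV, importance
  accounting) is correct on data with known structure.
* The UMAP stage wraps `uwot` with fixed-seed single-threaded SGD;
  embeddings are reproducible but, as always with UMAP, distances in
  the embedding are not calibrated quantities.
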