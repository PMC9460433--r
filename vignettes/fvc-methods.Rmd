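---
title: "Methods: object-based fractional vegetation cover from RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based fractional vegetation cover from RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvcmap)
```

## Problem and scope

Revegetation of mine tailings impoundments is monitored by the fraction of
the surface covered by vegetation (FVC). Centimeter-resolution UAV surveys
deliver an RGB orthomosaic and a dense, RGB-attributed 3D point cloud, but no
near-infrared band, so classical NDVI-style mapping is unavailable. `fvcmap`
implements the visible-band, object-based alternative end to end:

1. compute visible-band vegetation indices and choose one by statistical
   diagnostics;
2. segment the orthomosaic into image objects by multi-resolution region
   merging, with the scale chosen from a local-variance profile;
3. classify the objects with a bagged CART random forest and evaluate with a
   confusion matrix;
4. transfer the vegetation objects onto the point cloud and report FVC as a
   point fraction.

A synthetic scene generator stands in for field data; its role and limits are
discussed at the end.

## Visible-band indices and index selection

Nine indices are supported (`vi_names()`); each is evaluated per pixel on
real-valued bands, with chromatic coordinates `r = R/(R+G+B)` (likewise `g`,
`b`) where the formula uses them. Pixels where a formula's denominator
vanishes are set to `NA` rather than 0, because 0 is a meaningful index value
(a gray pixel has VDVI exactly 0). Every finite output provably lies inside
the index's theoretical range for valid 8-bit input; this is tested on a
million random pixels.

The classification index is selected in three stages
(`select_index()`):

1. **Range screening.** An index with observed values outside its theoretical
   range is discarded. On fully synthetic input this stage cannot fire (the
   formulas are range-bounded), but it matters for real rasters with
   overflow, nodata fill, or resampling artifacts.
2. **Bimodality screening.** A usable index should separate vegetation from
   background as two histogram populations. The gray histogram uses 256 bins
   spanning the theoretical range, so indices with very different occupied
   sub-ranges are binned on comparable grids. The histogram is smoothed with
   a 5-bin moving average; local maxima count as major peaks when their
   topographic prominence reaches 5% of the maximum smoothed count, and peaks
   closer than 10% of the *occupied* data range collapse onto the more
   prominent one. Measuring separation against the occupied range (not the
   theoretical one) is deliberate: narrow-band indices such as VDVI occupy a
   small sub-interval of [−1, 1], and no genuinely bimodal vegetation
   histogram could ever satisfy a separation rule quoted against the full
   theoretical width. Indices with fewer than two major peaks are discarded.
3. **Spread ranking.** Survivors are ranked by ascending mean per-class
   standard deviation (population SD over labeled pixels); ties fall back to
   the fixed `vi_names()` order. The winner is the classification index.

The thresholds (256 bins, window 5, prominence 0.05, separation 0.1) are
declared defaults, exposed as arguments; the screening outcome on the default
synthetic scene (VDVI chosen first) is locked in a test.

## Multi-resolution segmentation

Segmentation is bottom-up region merging on a 4-connected pixel grid. For a
candidate merge of segments 1 and 2 into m, the cost is

* color: `Δh_color = Σ_c w_c (n_m σ_c,m − (n₁ σ_c,1 + n₂ σ_c,2))`, with
  population standard deviations σ per layer c and layer weights `w_c`
  (default 1 for every layer);
* shape: `Δh_shape = w_smooth Δ(n·l/b) + w_cmpct Δ(n·l/√n)`, where `l` is the
  perimeter counted as exposed unit pixel edges (a single pixel has l = 4),
  `b` the shorter side of the axis-aligned bounding box in pixels, and each
  `Δ` is the merged value minus the sum of the parts;
* total: `C = w_color Δh_color + w_shape Δh_shape`.

Defaults are `w_color = 0.7` (spectral information should dominate shape) and
`w_smoothness = 0.4` / `w_compactness = 0.6`. The discretization conventions
(unit-edge perimeter, bounding-box short side, population SD) are stated here
because the criterion's symbols do not fix them.

The color change is always nonnegative (pooling never reduces total
area-weighted spread), but the shape change can be negative — merging two
halves of a square into the square *improves* both smoothness and
compactness — so the total cost of a shape-improving merge between
spectrally identical segments can dip below zero. This is a property of the
canonical criterion, not a bug; tests assert cost symmetry in general and
nonnegativity in the color-only configuration.

**Merge order and determinism.** The engine (C++, `src/merge.cpp`) repeatedly
merges the current global minimum-cost adjacent pair while that cost is below
`scale²`, with ties broken toward the smallest (id, id) pair; the surviving
segment keeps the smaller id, and ids start as row-major pixel order. The
global minimum edge is in particular a mutual best match for both endpoints,
so every executed merge satisfies local mutual-best fitting, and the run is
fully deterministic. A further consequence is that the merge sequence at
threshold T is a prefix of the sequence at any T′ > T, so segment counts are
monotone in scale. The same greedy procedure re-implemented naively in R
(recomputing every pair cost from scratch each iteration) serves as an oracle
in the tests: on hundreds of random 5×5 images the two produce identical
partitions. Floating-point contraction is disabled in the C++ build
(`-ffp-contract=off`) so both routes evaluate the identical IEEE expression.

**Scale selection (LV-ROC).** For each candidate scale L the scene is
segmented and the mean local variance LV(L) — the mean over segments of the
per-segment population SD, averaged over the spectral layers — is recorded;
`ROC(L) = (LV(L) − LV(L_prev))/LV(L_prev) × 100`, and the optimal scale is
the global ROC peak (the first scale has no ROC; scales after a zero LV are
skipped with a warning). The candidate grid should start above the pixel
noise floor (the conventional grid starts at 10 with step 10): relative
changes from near-zero LV at tiny scales would otherwise dominate the
profile. Elevation and slope can be appended as extra criterion layers; on
terrain-organized scenes this sharpens the profile and prevents segments from
straddling terrain breaks, which is tested directly.

## Random forest and evaluation

Each of K trees (default K = 75) is grown on a bootstrap sample of the n
training objects (n draws with replacement). At each node a random subset of
`ceiling(0.1 × n_features)` features (floor 1) is scanned; candidate
thresholds are midpoints between consecutive sorted unique values and the
split minimizing the sample-weighted child Gini impurity is taken, with ties
resolved toward the lower feature index and lower threshold. Growth stops at
depth 16, below 3 samples, or purity. Prediction is majority vote with ties
going to the first class in the canonical order (vegetation, bare land,
tailing sand, water). Tree i draws from the seed stream `seed + i`, so
forests are reproducible and partial retraining is stable. The default
hyperparameters (75, 16, 0.1, 3) are the grid-search-optimized values for
this class of scene.

Default object features: per-band mean and SD, mean of the chosen index,
mean elevation, mean slope, and area. The exact feature set is a declared
default of this package (the workflow it automates leaves it open), and the
feature table is a plain data frame, so alternatives are easy to supply.

Evaluation follows the standard confusion-matrix conventions with rows as
classification results and columns as reference: `PA_i = a_ii / a_ti`
(reference/column totals), `UA_i = a_ii / a_it` (classified/row totals),
`OA = Σ a_ii / N`, and kappa in the product form
`(N Σ a_ii − Σ a_ti a_it) / (N² − Σ a_ti a_it)`. The product form is the
standard chance-corrected statistic and reproduces the published kappa of the
reference confusion matrix to 3 decimals, which the sum-form variant
sometimes seen in print does not. PA of a class absent from the reference is
reported as `NA`, not 0.

## Cloud mapping, purge, and FVC

The orthomosaic and the point cloud share one georeferenced frame, so the 2D
to 3D transfer reduces to vertical projection: a point belongs to a
vegetation object when its (x, y) falls inside the object, boundary
inclusive (closed polygons; deterministic and conservative for FVC). A
general 11-parameter direct linear transform is out of scope. Two polygon
representations are supported: explicit rings (ray casting with an exact
on-edge test) and raster-backed segment objects (pixel lookup — exact
containment for pixel-aligned rectilinear boundaries, including holes). With
M vegetation objects of which N receive at least one point, the mapping
error statistic is Q = N/M × 100%.

Vegetation objects can contain residual bare-soil points (mixed objects at
class boundaries). `purge_bare_points()` removes vegetation-assigned points
whose per-point VDVI (from the point RGB) falls below a threshold. The
automatic threshold is the Otsu split of the within-vegetation VDVI values,
**guarded** by Otsu's separability ratio (between-class variance over total
variance at the optimum): the split is applied only when separability ≥ 0.8,
i.e. when the distribution actually shows two populations. An unguarded Otsu
split would always bisect a pure vegetation distribution (a unimodal normal
has separability ≈ 0.64) and destroy the estimate; the guard value 0.8 sits
between that and the ≈ 1 of genuinely two-spiked mixtures. In the manual
workflow this step is a human decision; the guard automates it.

Finally `FVC = 100 × vegetation points / total points`, reported in percent
to two decimals.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure the pipeline relies
on, not the physics of a survey:

* **Class geometry.** Two smooth Gaussian random fields (FFT-filtered white
  noise, correlation length 1/16 of the short grid side by default) are
  thresholded at rank quantiles: the first separates vegetation, the second
  splits the remainder into bare land, tailing sand, and water. Requested
  areal fractions are hit to within one pixel, and regions are contiguous
  blobs, which the segmentation stage needs. Default fractions: vegetation
  0.36, bare land 0.20, tailing sand 0.24, water 0.20 — a plausible partly
  revegetated impoundment with a pond.
* **Spectral model.** Per-class RGB means were fitted by least squares
  through the nine index formulas so that per-class index means approximate
  those of a real phosphate-tailings site (vegetation moderately green, bare
  land reddish, tailing sand bright gray, water dark blue-green); per-class
  VDVI means were kept apart within their published spread so the scene-level
  VDVI histogram is genuinely bimodal. Within-class variation is the sum of a
  brightness component (invisible to ratio indices), an anti-correlated
  red/blue component (broadens MRBVI/MGRVI/NGRDI without touching the green
  difference indices, reproducing the observed ordering of per-class spreads)
  and an iid floor. This is a calibration, documented as such — it is not
  ground truth, and passing tests on it show the pipeline's internal
  consistency, not field accuracy.
* **Terrain.** An eight-terrace stepped ramp spanning the configured relief
  (default 140 m — a dammed valley impoundment), with slope in degrees from
  central differences (one-sided at borders).
* **Point cloud.** Poisson(area × density) points (default 214.36 points/m²)
  uniform over the footprint, z bilinear from the elevation grid, RGB copied
  exactly from the enclosing pixel — so cloud and raster are color-consistent
  by construction.

What the generator does **not** emulate: photogrammetric reconstruction
artifacts (occlusion gaps, dome distortion, color balancing seams), shadows
and illumination gradients, spatially correlated texture within classes,
mixed pixels at boundaries, or canopy height structure (z carries terrain
only). Results on synthetic scenes therefore validate the algorithmic chain
— index math, merge engine, scale selection, forest, transfer arithmetic —
and the end-to-end error budget of that chain, but say nothing about
radiometric robustness on real surveys.

## Numerical choices and degenerate inputs

* Zero index denominators → `NA` (nodata), excluded from statistics,
  histograms, and segmentation.
* σ in the merge criterion is the population SD computed from running sums;
  negative variances from rounding are clamped at 0.
* Merge admission is strict (`cost < scale²`); at equal costs the smallest
  pair ids win, so runs are reproducible bit for bit.
* A scale grid with constant LV (e.g. a uniform image) has no ROC peak and is
  rejected with diagnostics rather than returning an arbitrary scale.
* Forests refuse single-class training sets and reject feature-column
  mismatches at prediction; class ties anywhere resolve to the canonical
  class order.
* `mapping_error()` requires M > 0; `fvc()` requires a positive total; a
  purge threshold above the maximum VDVI empties the vegetation set with a
  warning rather than an error.
* Histograms clamp values into the binning range, so counts always conserve
  the number of finite pixels.

## Problem sizes in the test suite

The bundled tests run the full pipeline on 256 × 256-pixel scenes at 0.08 m
(a 20.5 m square, ≈ 90,000 cloud points at the default density) with a
10-scale LV-ROC grid, and verify the merge engine against the exhaustive
oracle on 5 × 5 images; these sizes keep the whole suite within a couple of
minutes while exercising every stage at realistic parameter values. The
generator itself is routinely used at much larger grids; runtime is dominated
by the per-scale segmentation, which is near-linear in pixel count.

## Known limitations

* The LV-ROC global-peak rule inherits the method's sensitivity to the
  candidate grid: grids reaching deep into under-segmentation can move the
  global peak to a coarse, class-merging scale. Inspect the returned profile.
* The guarded Otsu purge assumes bare-soil contamination is the *minor* mode
  within vegetation objects; heavily mixed objects (approaching 50/50) can
  pass the guard and purge aggressively.
* Raster-backed polygon containment assigns points exactly on a shared pixel
  edge to the pixel they fall in under the half-open grid convention, which
  is a one-sided tie rule; explicit-ring containment is boundary-inclusive on
  both sides.
* The forest is a faithful, readable implementation tuned for hundreds to
  thousands of objects, not a high-performance learner for millions of rows.
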