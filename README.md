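# fvcmap

Object-based estimation of **fractional vegetation cover (FVC)** from
high-resolution UAV RGB orthomosaics and RGB-attributed dense point clouds,
for monitoring ecological restoration of mine tailings impoundments. The
package is aimed at remote-sensing practitioners who have only visible-band
imagery (no near-infrared) and want a fully scripted, reproducible version of
the standard eCognition-style workflow: visible-band vegetation indices,
multi-resolution segmentation, random-forest object classification, and
transfer of the classified 2D vegetation objects onto the 3D point cloud.

Because such surveys rarely come with public data, the package ships a
synthetic tailings-scene generator (4-class land cover, stepped terrain,
RGB-consistent point cloud) whose spectral model is calibrated so that the
per-class index statistics behave like a real phosphate-tailings site. Every
stage of the pipeline is exercised and tested against that generator.

## The method

* **Visible-band vegetation indices.** Nine indices computed per pixel from
  8-bit R, G, B (with chromatic coordinates r = R/(R+G+B) etc. where needed),
  including VDVI = (2G − R − B)/(2G + R + B), ExG = 2g − r − b, and
  CIVE = 0.44r − 0.88g + 0.385b + 18.78745. The classification index is
  chosen by screening: indices with values outside their theoretical range
  are discarded, then indices whose gray histogram shows no double peak, and
  the survivors are ranked by ascending mean per-class standard deviation.
* **Multi-resolution segmentation.** Bottom-up region merging under the
  weighted criterion C = w_color·Δh_color + w_shape·Δh_shape, where
  Δh_color = Σ_c w_c·(n_m·σ_c,m − (n₁·σ_c,1 + n₂·σ_c,2)) and the shape term
  mixes smoothness (n·l/b) and compactness (n·l/√n) changes; a merge is
  admitted while its cost is below scale². The scale parameter is selected
  from the rate of change of mean local variance (LV-ROC) across a candidate
  scale grid, optionally with elevation and slope as extra criterion layers.
* **Random forest.** Bagged CART trees with Gini-impurity splits
  (Gini(t) = 1 − Σ p(j|t)²; split score Σ nᵢ/n·Gini(i)), majority vote
  H(x) = argmax_Y Σ I(hᵢ(x) = Y); defaults: 75 trees, depth 16, 0.1 of the
  features per split, minimum split size 3. Accuracy is reported as
  producer's/user's accuracy, overall accuracy, and kappa from the confusion
  matrix.
* **2D → 3D mapping and FVC.** Vegetation objects are projected onto the
  point cloud (point-in-polygon, boundary inclusive); the mapping error is
  Q = N/M·100% where M is the number of vegetation objects and N those
  containing at least one point. Residual bare-soil points inside vegetation
  objects are purged by a guarded Otsu threshold on per-point VDVI, and
  FVC = 100 · vegetation points / total points.

## Worked example

```r
library(fvcmap)

run <- run_pipeline(pipeline_config(
  scene = scene_config(rows = 96, cols = 96),  # 7.68 m x 7.68 m @ 0.08 m
  seed  = 5))
run
#> <fvc_run>
#>   index VDVI | scale 20 | 112 segments
#>   held-out OA 1.0000, kappa 1.0000 (train 65 / test 47)
#>   M 28, N 28, Q 100.00%
#>   FVC 35.98% (truth 36.00%), 4560 / 12673 points
```

Reading the report: the index-selection diagnostics picked VDVI; the LV-ROC
profile put the optimal segmentation scale at 20, giving 112 image objects;
the forest classified the held-out objects perfectly; all 28 vegetation
objects received cloud points (Q = 100%); and the recovered FVC (35.98%) is
within a tenth of a point of the simulated truth (36.00%).

The evaluation operations work directly on any published confusion matrix:

```r
cm <- matrix(c(83, 1, 0, 0,
               4, 95, 0, 0,
               0, 0, 60, 0,
               0, 0, 1, 7), 4, 4, byrow = TRUE)
accuracy_report(cm)
#> <accuracy_report>
#>        [,1]  [,2]  [,3]  [,4]
#> PA    0.954 0.990 0.984 1.000
#> UA    0.988 0.960 1.000 0.875
#> OA 0.976  kappa 0.965  (N = 251)
```

A thin command-line front end over these functions is installed at
`inst/cli/fvcmap.R` (subcommands `simulate`, `indices`, `select-index`,
`select-scale`, `segment`, `classify`, `evaluate`, `map3d`, `fvc`, `run`).

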