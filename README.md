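# gliohbm

Glioma detection, grading and segmentation from T2-FLAIR brain MRI, for
researchers building or evaluating image-based computer-aided diagnosis
pipelines without access to large annotated cohorts.

The package implements three connected pieces:

* **Two-level histogram-based morphometry (HBM) classification.** Each
  (z-score-standardized) volume is tiled into square cells per axial
  slice and one histogram-of-oriented-gradients descriptor is computed
  per cell. Rather than concatenating descriptors, each cell *position*
  is encoded by fuzzy c-means: descriptors of all training subjects at
  that position are clustered into a disease-related and a
  health-related cluster (fuzzifier m = 2), and a subject's high-level
  feature at the position is its membership
  u = (1 + (d_disease/d_health)^{2/(m-1)})^{-1} to the disease centroid.
  The concatenated memberships feed a linear SVM with deterministic
  Platt calibration; score ≥ 0.5 predicts disease.
* **Exp-seg expanding segmentation.** From clinician seed polygons on a
  representative slice, the glioma region G is grown by alternating
  morphological dilation and voxel classification against the fixed
  normal region N, stopping when the glioma fraction of the expansion
  ring falls to a threshold in [0, 0.1]; results propagate to adjacent
  slices by projection, classifier filtering and erosion, in both
  directions.
* **Evaluation and phantoms.** Stratified repeated k-fold
  cross-validation with the whole pipeline refit per training fold, ACC /
  SEN / SPE and rank-based AUC pooled per run; and a phantom generator
  producing T2-FLAIR-like cohorts (smooth textured head, hyperintense
  ellipsoidal lesions with soft edges, ground-truth masks) so every stage
  is testable end to end.

Volumes are NIfTI-1 (`.nii`/`.nii.gz`), assumed co-registered and
bias-corrected upstream, axial slices along the last axis. Cohorts are
tibbles with list-columns; results are tibbles with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(gliohbm)

# Detection: 20 lesion phantoms vs 20 controls, lesion contrast 6x noise
cohort <- generate_detection_cohort(n_pos = 20, n_neg = 20, seed = 11) |>
  normalize_cohort()
report <- run_cv_experiment(cohort, k = 5, runs = 5, seed = 42)
glance(report)
#> # A tibble: 1 × 9
#>   cell_size accuracy_mean accuracy_sd sensitivity_mean sensitivity_sd
#>       <dbl>         <dbl>       <dbl>            <dbl>          <dbl>
#> 1        16          0.91      0.0122             0.88         0.0245
#> # ℹ 4 more variables: specificity_mean <dbl>, specificity_sd <dbl>,
#> #   auc_mean <dbl>, auc_sd <dbl>
mean(report$auc)
#> [1] 0.9825
```

Out-of-fold subjects are classified correctly about 91% of the time and
the pooled AUC is ≈ 0.98: at this contrast the lesion cells' gradient
structure separates cleanly. A label-permuted rerun of the same cohort
gives AUC ≈ 0.50 — the pipeline finds nothing when there is nothing.

```r
# Segmentation: ellipsoid lesion (radii 10 x 8 x 6), seeds on the central slice
ph <- generate_phantom(
  lesion = list(center = c(32, 32, 12), semi_axes = c(10, 8, 6),
                contrast = 60),
  texture_sd = 2, noise_sd = 5, seed = 3)
nv <- zscore_normalize(ph$volume, ph$brain_mask)
seeds <- tibble::tibble(
  slice = 12L, row = c(32, 30, 34, 16, 16, 24),
  col = c(32, 28, 36, 16, 26, 16),
  label = factor(c(rep("glioma", 3), rep("normal", 3)),
                 levels = c("glioma", "normal")))
res <- segment_volume(nv, seeds, brain_mask = ph$brain_mask,
                      threshold = 0.05, seed = 1)
res
#> <expseg_result 'phantom'> 2296 lesion voxels on 12 slice(s) (seed slice 12, threshold 0.05)
dice(res$mask, ph$lesion_mask)          # 3D overlap with ground truth
#> [1] 0.9232
dice(res$mask[, , 12], ph$lesion_mask[, , 12])   # seed slice
#> [1] 0.9644
```

Starting from a 9-voxel seed triangle, the region grows to the lesion
boundary and stops (Dice 0.96 on the seed slice), then propagates across
12 of the lesion's 13 slices without bleeding into lesion-free slices.

A command-line interface wrapping these functions ships in
`inst/cli/gliohbm` (subcommands `preprocess`, `train`, `predict`,
`segment`, `evaluate`, `simulate`; YAML config with flat dotted keys).
The methods vignette (`vignettes/gliohbm-methods.Rmd`) documents the
model, its parameters and its limitations.

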