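# lesionmapr

Lesion-symptom mapping and cross-validated lesion-load prediction for
stroke cohorts — with a synthetic-cohort generator so every stage can be
validated against known ground truth.

## The problem

In post-stroke aphasia, deficit severity correlates with both lesion
**size** and lesion **location**, and the two are confounded: larger
lesions cover more territory, so any frequently-damaged region looks
"critical" for any size-sensitive deficit. `lesionmapr` implements the
analysis pipeline that separates these contributions:

* **VLSM** — mass-univariate voxel-based lesion-symptom mapping: per
  voxel, the t statistic of the score on the voxel's damage value,
  corrected with **permutation-based continuous (generalized) FWER**:
  with order *v*, the null distribution of the *v*-th most extreme
  statistic over permuted scores bounds the probability of ≥ *v*
  false-positive voxels at level α.
* **SCCAN-style sparse LSM** — a sparse voxel-weight map `w`
  (‖w‖₂ = 1, at most `round(s·p)` nonzero entries) whose projection `Xw`
  of the lesion matrix maximally correlates with the score; the
  sparseness `s ∈ (0,1]` is optimized by 4-fold cross-validation with a
  bias toward sparser solutions.
* **dTLVC** — direct total lesion volume control: in the lesion matrix a
  damaged voxel of participant *i* carries `1/√V_i` (V_i = total
  lesioned voxels), down-weighting voxels of large lesions.
* **Lesion-load prediction** — 8-fold cross-validation: LSM templates are
  built from training folds only; each held-out participant's **template
  lesion load** `|lesion ∩ template| / |template|` enters a nested
  regression against lesion size:
  `ΔR² = R²(size + load) − R²(size)`, F-tested with 1 and n−3 df, plus
  the partial correlation of load and score controlling size.
* **PCA + varimax** — reduces a multi-measure behavioral battery to
  orthogonal deficit factors (Kaiser retention, regression-method factor
  scores).
* **Synthetic cohorts** — stochastic region-growing lesions over a
  vascular-territory probability field, with planted critical regions,
  deficit models (`score = c − w_size·z(size) − w_focal·z(load) + ε`) and
  a planted-factor battery.

## Worked example

```r
library(lesionmapr)

# a 128-participant synthetic cohort whose deficit is driven purely by
# damage to a 25-voxel planted region (plus noise, generative R^2 = 0.5)
sim    <- simulate_cohort(scenario_focal(n = 128, seed = 42))
cohort <- sim$cohort
cohort
#> <lesion_cohort> n = 128, lesion size 0.42-10.69 cc (mean 2.77)
#> <volume_geometry> 32x32x32 voxels @ 2x2x2 mm (0.008 cc/voxel)
#>   behavior: 1 measures

mask <- build_analysis_mask(cohort, min_frequency = 0.10)
mask
#> <analysis_mask> 1096 voxels at frequency >= 10% of n = 128

X <- dtlvc_normalize(cohort, mask)
y <- cohort$behavior$score

sm <- continuous_fwer_threshold(X, y, B = 1000, v = 100, alpha = 0.05, seed = 1)
sm
#> <stat_map> 1096 voxels, threshold -3.900 (v_eff = 1, alpha = 0.05,
#>            B = 1000), 208 survivors

dice_coefficient(vlsm_template(sm), sim$truth$regions$focal)
#> [1] 0.2151899

res <- run_study2(cohort, cohort$behavior["score"], config = list(B = 300, seed = 1))
res$comparisons[, c("method", "r2_size", "r2_load", "r2_both", "delta_r2", "p_value")]
#>   method r2_size r2_load r2_both delta_r2 p_value
#> 1   vlsm    0.14    0.44    0.45     0.31 1.1e-13
#> 2  sccan    0.14    0.37    0.40     0.27 1.3e-11
```

Reading the output: 208 of 1,096 analyzed voxels survive the corrected
threshold of t ≤ −3.90 and overlap the planted critical region
(Dice 0.22). In the prediction stage, lesion size alone explains 14% of
the deficit variance, but adding cross-validated template lesion load
raises R² to 0.45 (ΔR² = 0.31, p ≈ 1e-13) — lesion location carries
information beyond size, as it must for a focally-generated deficit. For
a size-driven deficit (`scenario_size_driven()`) the same pipeline yields
a non-significant ΔR², and that dissociation is the package's headline
validation.

A command-line wrapper lives at `inst/cli/lesionmapr.R`
(`simulate` / `map` / `predict` verbs over YAML configurations), and
`vignettes/lesion-symptom-mapping.Rmd` documents the model, parameters
and design decisions.

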