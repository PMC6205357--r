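---
title: "Lesion-symptom mapping and lesion-load prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-symptom mapping and lesion-load prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

After a left-hemisphere stroke, language deficits correlate both with *how
much* tissue is lost (lesion size) and with *where* it is lost (lesion
location). Because larger lesions cover more territory, the two are
confounded: any region frequently damaged by large lesions will appear
"critical" for any deficit that worsens with lesion size. This package
implements a pipeline that (i) maps lesion-deficit associations with two
families of lesion-symptom mapping (LSM) and (ii) quantifies, by
cross-validated prediction, whether lesion location carries information
*beyond* lesion size.

The full pipeline is:

1. **Cohort ingest** (`load_cohort`): binary 3D lesion masks in a common
   space plus a behavioral table; lesion size in cc is nonzero-voxel count
   times voxel volume.
2. **Analysis mask** (`build_analysis_mask`): only voxels lesioned in at
   least 10% of the cohort are analyzed — below that there is no usable
   contrast between damaged and intact participants.
3. **dTLVC normalization** (`dtlvc_normalize`): direct total lesion volume
   control. A damaged voxel of participant *i* carries `1/sqrt(V_i)`
   (`V_i` = total lesioned voxels of that participant, whole lesion), an
   intact voxel carries 0. Voxels from small lesions are weighted more,
   controlling lesion size at the voxel level. The identity
   `value^2 * V = 1` holds exactly and is unit-tested.
4. **Mass-univariate VLSM** (`voxelwise_statistic`,
   `continuous_fwer_threshold`, `vlsm_template`): a per-voxel t statistic
   (t-transform of the Pearson correlation between the voxel's damage
   value and the score) corrected by permutation-based *continuous
   (generalized) FWER*: with order `v`, the null distribution of the v-th
   most extreme statistic over permuted scores bounds the probability of
   `v` or more false-positive voxels at `alpha`.
5. **Sparse multivariate LSM** (`sccan_fit`, `optimize_sparseness`,
   `sccan_template`): an SCCAN-style sparse voxel-weight map whose lesion
   matrix projection maximally correlates with the score; the sparseness
   parameter `s` (fraction of voxels retained) is chosen by 4-fold
   cross-validation with a deliberate bias toward sparser solutions.
6. **Lesion-load prediction** (`run_study2`): 8-fold cross-validation;
   per fold an LSM template is built from the training participants only,
   and each held-out participant's *template lesion load* — the proportion
   of the template inside their lesion — becomes a predictor. Nested OLS
   regression (`compare_models`) then tests whether load improves on size:
   `delta R^2 = R^2(size + load) - R^2(size)`, F test with 1 and n − 3 df,
   plus the partial correlation of load and score controlling size.
7. **Behavior-side control** (`behavior_residual_control`): the
   conservative alternative of residualizing the score on lesion size
   before mapping.

# Deficit coding and test direction

Scores are coded *higher = better* (accuracy-style). Damage therefore
predicts lower scores, and the voxelwise test is one-sided toward negative
statistics; a `two.sided` alternative exists. SCCAN weights are oriented
so the projection correlates negatively with the score; downstream
consumers use only the support.

# Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_frequency` | 0.10 | proportion | voxels lesioned in <10% of the cohort carry almost no contrast |
| `B` | 1000 (300 inside the 8-fold pipeline) | permutations | null-quantile Monte-Carlo error well below the decision scale |
| `v` | 100 | voxels | tolerated false-positive count of the generalized FWER, defined for ~150,000-voxel brain masks |
| `alpha` | 0.05 | level | conventional |
| `s` grid | 0.005–1.0 (10 values) | fraction | log-ish coverage of focal and diffuse regimes |
| `tolerance` | 0.02 | CV correlation | sacrifice accepted for a sparser solution |
| inner folds | 4 | — | sparseness optimization CV |
| outer folds | 8 | — | template/lesion-load cross-validation (n = 128 gives 16 per fold) |

**v rescaling.** `v = 100` was designed for full-brain masks of roughly
150,000 voxels. On a desk-scale mask of ~1,300 voxels a fixed `v = 100`
would be structurally liberal (it would tolerate 8% of the mask as false
positives), so the effective order is scaled with mask size:
`v_eff = max(1, round(v * p / 150000))`. `scale_v = FALSE` restores the
literal order.

**Quantile convention.** The permutation threshold uses a nearest-rank
rule: the `max(1, floor(alpha * (B + 1)))`-th smallest null order
statistic over `B` Monte-Carlo permutations, or
`max(1, floor(alpha * n!))` under exhaustive enumeration (`exact = TRUE`,
available for n ≤ 8 and used by the oracle tests). Ties at the threshold
are included among survivors — reproducible and conservative.

**Sparse fit.** `sccan_fit` initializes the weight vector from voxel-score
correlations, keeps the `round(s * p)` largest magnitudes, renormalizes to
unit L2 norm, and re-estimates from the score component captured by the
current projection until the support stabilizes (cap 100 iterations). At
`s = 1` the constraint is inactive and the closed-form solution
(proportional to `X'y`) is returned. An optional 26-neighbour smoothing
prior (`smooth`) pulls supports toward spatially coherent clusters; it is
off by default because it trades held-out accuracy at small `s` for
tidier supports.

**CV correlation.** Held-out projections are mapped to the score scale by
the training fold's linear calibration (intercept and slope of training
scores on the training projection) before pooling; the pooled Pearson
correlation with the observed scores is the reported CV correlation.
Without the calibration the per-fold projections have arbitrary scale and
a sign fixed only by convention, which makes pooling across folds
incoherent.

# The synthetic cohort generator

No patient data ship with the package; every analysis is validated on
synthetic cohorts with known ground truth (`simulate_cohort`).

* **Territory** (`make_territory`): an anisotropic Gaussian probability
  field truncated at Mahalanobis radius 2 — a stand-in for the left
  middle-cerebral-artery territory. Default desk grid: 32^3 voxels at
  2 mm, territory centred at (11, 16, 16) with scale (6.5, 8, 6.5),
  giving a ~7,800-voxel support and the centre-heavy overlap map typical
  of stroke cohorts.
* **Lesions** (`simulate_lesion`): stochastic region growing. A seed voxel
  is drawn proportionally to the territory field; the 26-connected
  frontier is then sampled with weight `territory probability ×
  (lesioned-neighbour count)^compactness` until the target size is
  reached. `compactness = 2` acts as surface tension: concavities fill
  first and lesions are spatially coherent, as vascular infarcts are.
  With `compactness = 0` (rough Eden growth) the damage indicators of
  neighbouring voxels decorrelate almost completely, which no real lesion
  data show. Region growing makes larger lesions engulf more of any
  critical region — the size-location coupling the pipeline is about.
* **Sizes**: truncated lognormal calibrated to a chronic left-hemisphere
  stroke cohort (mean 100.97 cc, SD 82.76, range 5.38–376.12 cc;
  `meanlog = 4.3578`, `sdlog = 0.7170`), with volumes scaled by
  `size_scale = 1/32` so the desk grid preserves a usable ratio between
  lesion extent, territory and critical-region size. A paper-scale
  configuration (4 mm voxels, `size_scale = 1`) reproduces the 5.38–376.12
  cc range directly and is exercised in the tests.
* **Deficits** (`generate_deficits`):
  `score = c − w_size·z(size) − w_focal·z(load) + ε`, `ε ~ N(0, noise_sd)`,
  where `load` is the damaged fraction of a planted critical region. The
  presets `scenario_focal()` (w_size = 0, w_focal = 1, noise 1) and
  `scenario_size_driven()` (w_size = 1, w_focal = 0, noise 1) both have a
  generative R² of w²/(w² + σ²) = 0.5 — strong but noisy, as real deficit
  scores are. The focal preset plants a 25-voxel region (~2% of the
  analysis mask) at the territory centre.
* **Battery** (`generate_battery`): a 17-measure battery with 3 planted
  factors. Latent factors are built from the damaged fractions of three
  disjoint planted regions, z-scored and ZCA-orthogonalized by default.
  The orthogonalization is needed because raw region loads share
  lesion-size variance and are therefore mutually correlated, whereas the
  generative model (and the PCA-varimax recovery target) is orthogonal;
  ZCA keeps the latents maximally close to the raw loads. Measures are
  `latents %*% t(loadings)` plus independent uniqueness noise
  (loadings 0.8 primary / 0.1 cross, uniqueness SD 0.53, giving ~70–76%
  retained variance for the 3-factor solution).

**What the generator does not emulate.** Real lesions follow vascular and
gyral anatomy, not an ellipsoidal Gaussian; masks come from manual
segmentation and template registration with their own error; deficit
scores are bounded and skewed rather than Gaussian; and a real brain mask
has ~150,000 voxels against ~1,300 here. Passing tests therefore show the
*methods* behave as designed under the stated statistical structure — not
that effect sizes or template anatomies transfer to clinical data.

# Factor analysis of the behavioral battery

`fit_pca_varimax` z-scores the measures, takes principal components of
the correlation matrix, retains components by the Kaiser rule
(eigenvalue > 1.0) or a fixed count, and varimax-rotates the retained
loadings with Kaiser row normalization. Retention precedes rotation.
Factor scores use the regression method (`R^{-1} Λ` applied to z-scored
measures); regression scores preserve the rank ordering that downstream
mapping consumes. Factor recovery is assessed by Tucker congruence after
optimal sign/permutation alignment, since rotation leaves column sign and
order indeterminate.

# Numerical choices and degenerate inputs

* Zero-variance voxels (damaged in all participants of a training fold
  with equal lesion size, or never damaged) are excluded from testing with
  a warning.
* Numerically perfect voxel-score associations are capped at |t| = 1e6.
* A constant deficit score yields an *empty* statistic map and zero
  lesion loads rather than an error, keeping batch pipelines alive.
* An empty training template assigns load 0 to its held-out participants
  (with a warning) rather than dropping them, keeping the design balanced.
* A constant predictor in the nested regression is flagged `degenerate`
  and its model's R² reported as 0; perfectly collinear size/load gives
  `delta_r2 = 0`, `partial_r = 0` exactly.
* Sparseness values retaining zero voxels (`round(s·p) < 1`) are an error
  in `sccan_fit` and skipped with `NA` in the grid search.
* All randomness flows from integer seeds through a deterministic
  sub-seed derivation; every simulation, fold split and permutation run is
  bit-reproducible from one master seed, and RNG state is restored after
  each seeded operation.

# Design choices where the design was open

* **"Stepwise regression"** is implemented as the explicit hierarchical
  comparison of the three models actually reported (size; load;
  size + load) — no automated entry/exit search, which would obscure the
  single question being asked.
* **Analysis mask per training fold**: rebuilt from training participants
  only (strict no-leakage reading); a `rebuild_mask = FALSE` toggle keeps
  the full-sample mask for users who prefer a fixed voxel set.
* **Permutations resample the behavior side**, preserving the lesion
  covariance structure.
* **dTLVC volume unit** is voxel count; the constant factor cancels in all
  correlation-based statistics. Lesion size as a regression predictor is
  reported in cc and z-scored inside the models.
* **Region summaries** (`region_overlap_summary`) default to percent *of
  the region* covered; the denominator is switchable to the template side
  because both conventions exist in the literature.
* **Sign-flip robustness**: factor scores are sign-indeterminate, so the
  two-sided mapping path and all R²/F statistics are invariant to score
  negation (tested).

# Problem sizes used by the test suite

The suite validates on desk-scale cohorts: null calibration on a 20^3
grid (n = 60, B = 500, 200 Monte-Carlo runs), planted-region recovery and
sparseness adaptivity on the 32^3 default conditions (n = 128, 20 seeds),
and the size/location dissociation over 40 replicate cohorts per scenario
with B = 300 and 8 outer folds. Exact-arithmetic checks (dTLVC identity,
lesion-load fractions, oracle equivalences at 1e-10) run on constructed
micro-datasets.

# Known limitations

* At desk scale the spatial correlation length of lesion damage is large
  relative to a ~25-voxel critical region. Mass-univariate templates
  therefore include a genuine "halo" of correlated neighbours several
  times the region's size, and Dice overlap with the planted region
  saturates around 0.25–0.35 even when the underlying statistic map ranks
  the region correctly. Likewise, because a sizable fraction of the small
  mask carries indirect signal, the dense (s = 1) SCCAN solution predicts
  held-out scores about as well as sparse ones and the
  sparsest-within-tolerance rule selects s = 1 in a substantial minority
  of focal replicates. Both effects shrink as the mask grows toward
  real-data scale; the dissociation analyses (which depend on lesion
  *load*, not template tightness) are unaffected.
* The sparse fit is a truncated-projection algorithm in the SCCAN family,
  not a numerical replica of any specific implementation; only its
  documented contract (sparseness fraction, CV objective, sparser-solution
  bias) is matched.
* One deficit score is mapped at a time; truly multivariate behavior-side
  CCA is out of scope.
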