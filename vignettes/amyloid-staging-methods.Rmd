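---
title: "Reference-free amyloid-PET staging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free amyloid-PET staging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`amystage` implements a machine-learning pipeline that stages cerebral
amyloid-beta deposition from a single florbetaben PET scan and its
anatomical parcellation, without requiring a normative reference
database. Staging is hierarchical:

* **Stage 0** -- no significant cortical amyloid,
* **Stage 1** -- cortical amyloid without striatal involvement,
* **Stage 2** -- cortical *and* striatal amyloid.

The pipeline emulates the clinical visual-read workflow. A trained
reader scores eight cortical regions (frontal, precuneus / posterior
cingulate, lateral temporal, parietal; each left and right) on a 1-3
regional cortical tracer uptake (RCTU) scale, condenses them to a
brain amyloid plaque load (BAPL) score by the maximum rule, and calls
the scan positive when BAPL >= 2. `amystage` learns to reproduce those
reads from image-derived features and then extends them with a
striatal step that visual reading does not provide.

# Pipeline stages

## 1. Slice selection (`select_slices`)

All reading happens on five canonical axial slices, indexed
superior-to-inferior: plane `k` of a `K`-slice volume has
superior-inferior index `s = K - k + 1`.

* `SN_top` (S1): the most superior slice containing lateral-ventricle
  voxels.
* `SN_bottom` (S4): the superior-inferior centre of mass of nine
  temporal-lobe parcels, rounded to the nearest slice.
* S2 and S3: `round(SN_top + 0.25 * D)` and `round(SN_top + 0.5 * D)`
  with `D = SN_bottom - SN_top`.
* S5: the rounded centre of mass of the caudate and putamen (the
  striatal slice).

Rounding uses R's `round()`, i.e. IEEE round-half-to-even. Note a
subtlety: at exact `.5` fractions, half-to-even rounding is
translation-equivariant only for shifts that preserve parity (even
shifts). The package keeps the half-to-even rule throughout and the
test-suite's equivariance checks use geometries whose quarter and half
interpolants are exact integers, or even shifts, where equivariance
holds for any offset.

## 2. Feature extraction (`subject_features`, `uptake_curve`)

Each cortical ROI is read on its designated slice (frontal on S3,
precuneus/PCC on S2, lateral temporal on S4, parietal on S1). Slice
intensities are normalized by the mean PET value over the eight
cortical ROI masks, so the cortical union has mean 1 by construction;
this plays the role of the reference-region normalization that the
method deliberately avoids.

For each ROI, an *uptake curve* summarizes how tracer signal decays
with distance from the cortical ribbon into the white matter:

1. The propagation domain is the ROI's grey matter plus the white
   matter within `dilate_px` (default 20) pixels of it.
2. Geodesic distance from the grey-matter seed is computed inside the
   domain (see below).
3. `[0, d_max]` is split into `n_bins` (default 15) equal bins; the
   mean normalized intensity of the first `n_used` (default 12) bins
   forms the feature vector. Empty interior bins are filled by linear
   interpolation (`stats::approx`, `rule = 2`), which can occur for
   thin or fragmented ROIs.

The defaults (15 bins, first 12 used) keep the curve inside the
well-populated part of the distance range; the last bins are sparse
and noisy because few pixels reach maximal distance.

### Geodesic distance (`geodesic_distance`)

Distances are quasi-Euclidean: front propagation on the 8-connected
pixel graph with step weights 1 (axial) and `sqrt(2)` (diagonal),
scaled by the pixel spacing, implemented as a Dijkstra
priority-queue sweep in C++. This is the same discrete geodesic
transform that MATLAB's `bwdistgeodesic` (`'quasi-euclidean'`)
computes. It is a chamfer metric, not a first-order Eikonal solution;
the two differ by up to ~8% on off-axis straight-line paths, but the
chamfer metric is exactly reproducible, monotone along fronts, and is
the metric the package's own brute-force Dijkstra oracle validates to
floating-point precision.

### Striatal feature (`striatal_feature`)

The striatal feature is the vector of normalized intensities of the
template striatal mask pixels on S5, in fixed row-major order. When
subject and template grids differ by a translation,
`registration = "affine"` estimates the integer shift by exhaustive
overlap search (`max_shift` default 8 px) before sampling; full affine
or deformable registration is out of scope and the interface is
deliberately pluggable.

## 3. Staging model (`fit_staging_model`, `predict_stage`)

* **pRCTU regression:** one support-vector regressor per cortical ROI
  (linear kernel, cost 1, no kernel scaling) maps the 12-bin curve to
  a continuous *pseudo-RCTU* in the 1-3 range. The epsilon-insensitive
  band is `IQR(y) / 13.49`, the classical rule that makes epsilon
  approximately one residual standard deviation for Gaussian noise.
* **Step 1, cortical classification:** a linear SVM on the eight
  pRCTU values separates amyloid-positive (BAPL >= 2) from negative
  scans. The decision value is oriented so positive class means
  positive decision; a decision of exactly 0 is called positive
  (ties break toward sensitivity).
* **Step 2, striatal classification:** only for cortically positive
  scans. PCA (centred, unscaled) reduces the striatal pixel vector,
  keeping components to 95% explained variance capped at
  `n_train - 2`; LDA on the scores yields the stage-1 / stage-2 call
  (decision = log posterior ratio). `method = "svm"` substitutes a
  linear SVM for LDA; the two agree closely on the synthetic cohorts
  and the swap is covered by a robustness test.

A configuration hash binds fitted models to the feature-extraction
settings; `predict_stage` refuses features produced under a different
configuration.

## 4. Evaluation (`loocv_evaluate`)

Leave-one-out cross-validation refits the *entire* pipeline per fold:
the eight regressors, the cortical SVM (on in-fold pRCTU), and the
striatal classifier (on the fold's cortically positive subjects). The
report gives the 3x3 confusion matrix, overall accuracy, step-1
metrics on all subjects, step-2 metrics on truly positive subjects,
areas under the ROC curve from the continuous decisions, and macro
one-vs-rest sensitivity/specificity.

Truth can be the visual read (`truth = "visual"`) or a SUVr-based rule
(`truth = "suvr_cutoff"`): cutoffs are `mean + 2 SD` of a reference
group after iteratively removing > 2 SD outliers
(`iterative_outlier_cutoff`), applied to global and striatal SUVr
(whole cerebellum reference for both).

## 5. Discriminative patterns (`cortical_pattern`, `striatal_pattern`)

The linear weight vectors of the fitted classifiers are normalized by
their maximum absolute value, giving signed scores in `[-1, 1]`. Signs
are preserved deliberately: a negative weight is information (a region
or pixel whose *lower* uptake indicates positivity), and clipping to
`[0, 1]` would discard it. The striatal pattern can be rendered back
onto the template mask as a 2-D map.

## 6. Outcome statistics (`ancova_compare`, `prctu_regression`, `mediation_path`)

* `ancova_compare`: covariate-adjusted stage means via `lm` +
  `emmeans`; pairwise contrasts with raw p-values and Bonferroni
  correction (`p_corrected = min(1, 3p)` for the three pairs); a
  linear trend contrast `(-1, 0, 1)` across stages.
* `prctu_regression`: OLS of an outcome on mean pRCTU plus
  covariates, optionally restricted to amyloid-positive subjects.
* `mediation_path`: the two-equation OLS mediation model
  (stage -> mean pRCTU -> outcome) with covariates. Estimates the
  paths a, b, direct effect c', total effect c; the identity
  `c = c' + a*b` holds exactly for OLS. The indirect effect gets a
  percentile bootstrap CI (default 2000 resamples) and a Sobel test.
  Verdicts: *complete* (indirect significant, direct not), *partial*
  (both significant, same sign), *inconsistent* (both significant,
  opposite signs), *none*. The verdict intentionally does not gate on
  the total effect being significant, since suppression can mask a
  real indirect path. Rows with missing values are dropped listwise.

# The synthetic validation cohort

No clinical data ships with the package; everything is validated on
synthetic phantoms whose ground truth is known exactly
(`make_phantom`, `make_cohort`). The generator's defaults *are* the
study conditions -- they are fixed design choices, not tuning knobs.

A phantom (default 64 x 64 x 48 voxels) contains a brain ellipsoid
with a 4-voxel cortical ribbon, white matter, lateral-ventricle boxes,
nine temporal parcels, caudate and putamen, a cerebellar slab, and
four cortical sectors per hemisphere matching the eight read regions.
PET intensity is piecewise constant -- white matter `W = 100`,
ventricles `0.25 W`, cerebellum `0.70 W`, grey matter
`W * (0.55 + 0.30 * (r - 1))` for regional RCTU `r` in `[1, 3]` (so
grey crosses white at r = 2.5, mimicking loss of grey-white contrast
with amyloid load), striatum at the striatal severity level -- then
smoothed with a Gaussian point-spread function (sigma = 1 voxel) and
degraded with Gaussian noise (SD 3, i.e. 3% of white matter).

Cohorts draw stage labels with probabilities (0.374, 0.104, 0.522),
matching a memory-clinic case mix; per-region RCTU severities,
striatal severity, demographic covariates, and clinical outcomes come
from simple generative models (`default_outcome_models`). Outcomes are
built so that stage effects are *completely mediated* by amyloid
burden by default (`beta_x = 0`); setting `beta_x != 0` plants a
direct path for testing partial mediation. An optional
`label_flip_rate` simulates inter-reader disagreement.

What the generator emulates: the geometry the slice selector needs,
the grey/white uptake inversion that drives the curve features, the
striatal involvement contrast, realistic stage proportions, and
outcome structure with known mediation. What it does not: real
anatomy, scanner-specific PSF anisotropy, partial-volume effects
beyond simple smoothing, registration error beyond translation, or
non-Gaussian noise.

# Problem sizes and reproducibility

The package's own validation uses: a 90-subject cohort under full
per-fold-refit LOOCV (staging accuracy, pRCTU-SUVr agreement), 50
random domains for the geodesic oracle comparison, 200 replicate
cohorts of n = 300 for mediation-verdict recovery, and 500 replicates
for ANCOVA null calibration. All randomness is seed-derived;
`make_phantom`/`make_cohort` save and restore the caller's RNG state.

`scripts/acceptance.R` recomputes the headline quantities against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

# Limitations

* The parcellation must already be in subject PET space; only
  translation misalignment of the striatal slice is handled.
* SVR/SVM hyperparameters (linear kernel, cost 1) are fixed, not
  cross-validated; the method is designed to be reference-free and
  parameter-light rather than maximally tuned.
* The half-to-even rounding / translation-equivariance tension
  described above is inherent to integer slice selection.
* Mediation inference assumes the standard no-unmeasured-confounding
  conditions; the synthetic cohorts satisfy them by construction, real
  data need not.
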