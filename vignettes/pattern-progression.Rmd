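---
title: "Longitudinal pattern expression: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal pattern expression: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `brainpattern`, the
parameters that matter, the generative model of the synthetic cohorts, and
the design decisions taken where the methodology left genuine freedom.

## The scientific question

Cross-sectional work shows that structural-MRI classifiers separate
chronic schizophrenia patients from controls much better than
first-episode patients. Two mechanisms could produce that: (a) the
disorder-specific gray-matter pattern itself becomes more strongly
expressed as the disorder progresses, or (b) patients drift away from the
normal brain-aging trajectory in a non-specific way that any
age-sensitive model picks up. Disentangling the two requires following the
*same* subjects over years and measuring, at each timepoint, the
expression of (i) a disorder-vs-control pattern and (ii) a normative
brain-aging pattern, both learned in *independent* cohorts and applied
without retraining. `brainpattern` implements that design end to end.

## Pattern expression models

### Preprocessing chain (fit/apply discipline)

Every preprocessing step is a fit/apply pair. Fitting functions receive
only training-row indices, so no information can leak from held-out or
external subjects; this is enforced structurally (the API passes training
rows only) and verified by tests that mutate held-out rows and assert the
fitted state is unchanged.

* **Control-based z-normalization** (`fit_znorm`/`apply_znorm`):
  `z = (x_i − μ_HC)/σ_HC` per voxel, with μ/σ estimated from a dataset's
  own healthy controls. This is applied once per dataset *before* any
  modelling, because its purpose is the removal of per-scanner intensity
  offsets and scalings — each cohort is measured on its own instrument.
  SDs below `1e-6` density units are floored at that value so empty
  voxels cannot blow up the division; only near-constant voxels are
  affected.
* **Gaussian smoothing** (`gaussian_smooth`): separable kernel with
  `σ = FWHM/(2√(2 ln 2))` per axis in voxel units. Boundaries are handled
  by reflection about the volume edge (half-sample convention), which
  makes the 1-D convolution matrices symmetric and doubly stochastic:
  constant volumes are unchanged and total gray-matter mass is preserved
  exactly. Smoothing is treated as an outermost hyperparameter: the
  smoothed versions of a dataset are precomputed once per FWHM and the
  inner CV selects among them, which is identical to re-smoothing inside
  each fold at a fraction of the cost.
* **Covariate regression** (`fit_covariate_regression`): per-voxel OLS
  with intercept. For the classifier it is fitted on the training-fold
  *controls* only, so that patient-related variance is not absorbed into
  the nuisance model; for the (healthy) brain-age cohort it is fitted on
  all training rows. Applying the fit subtracts the slope terms only and
  keeps the intercept, i.e. maps are recentred to the reference
  population's mean structure rather than to zero. Subtracting the full
  fitted value including the intercept would only shift every subject by
  the same constant per voxel and leave all downstream statistics that
  compare subjects unchanged; we document the choice and keep slope-only
  subtraction.
* **PCA** (`fit_pca`): centred, components ordered by decreasing
  variance, retaining the smallest k whose cumulative explained-variance
  ratio reaches the target (default 0.80). Each component's
  largest-magnitude loading is made positive so back-projected weight
  maps are reproducible across runs.
* **Min–max scaling** (`fit_minmax`): `(x − min)/(max − min)` with
  training bounds; constant features map to 0, and held-out values
  outside the training range are deliberately *not* clipped — the linear
  decision function extrapolates, and clipping would distort external
  cohorts with wider feature ranges.

### Nested cross-validation

The outer cycle (CV2, default 10 permutations × 10 folds; all tests and
the acceptance pipeline use 3 × 3 to stay within desk-scale budgets)
estimates generalization; the inner cycle (CV1, default 10 × 5, scaled
3 × 2) selects hyperparameters. Folds are stratified by class for the
classifier and by age decile for the regressor (the methodology we follow
does not state a regression stratifier; deciles keep the age distribution
balanced across folds).

For each outer training partition, every (FWHM, C) — or (FWHM, ν) —
combination is fitted on each inner training set and evaluated on the
inner test sets; the combination with the best mean inner metric
(maximal balanced accuracy, or minimal MAE) wins, and its inner-fold
models are retained as the partition's ensemble. Two open choices were
resolved as follows:

* **Ties** break toward smaller cost, then smaller ν, then smaller FWHM:
  deterministic, with a parsimony bias toward stronger regularization and
  less smoothing.
* **Retained models**: the winning combination's inner-fold models
  themselves are kept (rather than one model refitted on the full outer
  training partition). The underlying framework's behaviour is not fully
  specified on this point; retaining inner-fold models makes the
  cross-validation ratio map (below) well defined and changes results
  only marginally. Tests therefore target invariants (no leakage,
  order-invariant aggregation), not this choice.

A subject's **pattern expression** is the arithmetic mean of the decision
values `w·x + b` of the contributing models: the owning partition's models
for outer-test subjects, and *all* retained models for external (OOCV)
subjects. The mean is the natural order-invariant aggregator and matches
the default behaviour of ensemble application in this family of tools.
External cohorts are z-normalized with their own controls and receive no
retraining of any kind.

The linear SVM and ν-SVR are solved by LIBSVM (via `e1071`); the
contract is only the linear decision function `w·x + b`, which the package
extracts explicitly and validates against the solver's own predictions.

### Brain-age gap and detrending

BrainAGE is `predicted − chronological` age. Brain-age models
overestimate young and underestimate old subjects, so a linear correction
is fitted by OLS of the outer-test residuals on chronological age and
applied unchanged to external cohorts (the same "no retraining" logic as
for the classifier). Only the linear (degree-1) detrend is implemented —
the minimal reading of residual-on-age fitting; on the fitting set the
detrended gap has exactly zero age slope and zero mean by the OLS normal
equations, which the tests assert to machine precision.

## Statistical toolkit

* **Balanced accuracy** is the mean of sensitivity and specificity at
  decision threshold 0 (the standard SVM operating point).
* **ROC/AUC** uses the Mann–Whitney U with ties counted one half;
  equality with exhaustive pair counting is asserted in tests.
* **DeLong tests** are implemented from placement values, with the paired
  variance including the placement covariances and the unpaired variance
  dropping them; the implementation is cross-checked against `pROC` (an
  independent implementation) and against bootstrap variances.
* **Demographic tests**: Welch t with Satterthwaite df (computable from
  printed group summaries), Cohen's d with (n−1)-weighted pooled SD, and
  Pearson χ² *without* continuity correction — the combination that
  exactly reproduces demographic statistics printed in this literature.
* **Mixed models**: `response ~ x * time + covariates + (1 | subject)`,
  REML, Satterthwaite F for the interaction (via `lmerTest`).
  R² is reported as the standard marginal/conditional decomposition
  (fixed-effects variance over fixed + random-intercept + residual;
  conditional adds the random-intercept variance to the numerator). The
  literature contains several mixed-model R² variants; the standard
  decomposition is substituted and both values are reported.
* **Permutation prognostic AUC**: the outcome labels are permuted
  (default 5,000 times) and the observed AUC compared two-sidedly via
  `|AUC − 0.5|`, with the add-one estimator
  `p = (1 + #extreme)/(n_perm + 1)` — valid p-values, never exactly zero.
* **KNN imputation**: missing cells take the mean of the k nearest rows,
  with Euclidean distances over mutually observed, standardized columns;
  outcome columns are excluded from both imputation and distances to
  avoid outcome leakage. Outliers are flagged strictly outside
  mean ± 3 SD.

## Voxelwise inference

For a balanced two-timepoint design with subject as the random factor,
the mixed-effects interaction between a per-subject expression difference
and timepoint is algebraically equivalent to the between-subject
regression of within-subject difference images on the score differences.
The package computes exactly that per-voxel slope t/F statistic: it is
exact, fast, and its null distribution is verified against the
theoretical F distribution in tests.

Inference uses TFCE,
`TFCE(v) = Σ_h e(v,h)^E · h^H · dh`, with the method's standard exponents
E = 0.5, H = 2, integration step dh = max/100, and 6-connectivity by
default (18/26 available). Two-sided inference runs TFCE on the positive
and negated map separately, so decreases and increases are enhanced
independently. Family-wise error is controlled by the permutation
distribution of the maximum TFCE statistic across both signs, permuting
by **subject-level sign flips of the per-voxel-centred difference
images** — the exchangeability unit of a paired design. When fewer than
`n_perm` distinct sign patterns exist the flips are enumerated
exhaustively (with a warning). Corrected
`p(v) = (1 + #{max_π ≥ TFCE(v)})/(n_perm + 1)`.

## Reliability maps

Model weights live in PCA space; `backproject()` propagates them through
the chain's linear steps (dividing by the min–max training range,
multiplying by the PCA basis). Smoothing and z-normalization are not
inverted: maps live in preprocessed voxel space, since those steps are
not meaningfully invertible subject-wise. The cross-validation ratio is
the per-voxel **median across fold maps divided by their standard error**
(SD/√k), with a signed cap of 1e6 where the SE underflows and the
conventional reliability threshold |ratio| ≥ 3. The phrase "sum of the
median weights … divided by the standard error" in the source
methodology is ambiguous; the median/SE reading is the default and the
sum-of-per-group-medians numerator is available behind the
`numerator = "sum_of_medians"` flag.

## The synthetic cohort generator

The simulator emulates the study design the pipeline was built for: a
wide-age multi-site discovery cohort, a large healthy training cohort for
the brain-age model, and a narrow-age birth cohort followed at two
timepoints ~9 years apart.

The clean map of subject *i* is

```
x_i(v) = B(v) − aging_slope·A(v)·age_i − δ·σ_noise·P(v)·(1 + ρ·duration_i)·1[patient]
```

followed by the subject's site affine (`scale_s·x + offset_s`), additive
Gaussian noise, and clipping at zero (density is non-negative; clipping
slightly biases means upward where B(v) is small). B(v) is a smoothed
random field around `baseline_mean`; P and A are compact cuboid voxel
sets with a configurable overlap fraction (realised to whole-column
granularity).

Default parameters, chosen once as realistic study conditions:

* `grid_shape = 16³` (tests and the acceptance pipeline use 8³ — the
  package's chosen desk-scale problem size), `voxel 2 mm`,
  `baseline_mean = 0.5`, `noise_sd = 0.1`: typical VBM density scales.
* `disorder_effect δ = 0.8` — a large single-voxel standardized effect;
  over a ~27-voxel pattern this yields discovery-cohort separability at
  the upper end of what disorder classifiers achieve, making planted
  truth clearly recoverable.
* `progression_rate ρ = 0.04`/year — ~27 % growth of the disorder
  deficit over 30 years of illness and ~+0.03 density units over a
  9-year follow-up. With the default cohort sizes (29 patients, 61
  controls) this reproduces the magnitude of decision-score × timepoint
  interactions reported for real longitudinal birth-cohort data
  (F ≈ 10–15), which is what "realistic" means here.
* `aging_slope = 0.003` density/year over a 66-year age range.
* two sites with offsets (0, 0.05) and scales (1, 1.05) — the size of
  between-scanner differences that motivates control-based
  z-normalization.
* `overlap_fraction = 0.25`: the disorder and aging patterns share a
  quarter of their voxels, so the two expression measures correlate
  moderately, as observed empirically.
* `cohort_age = 33.7 ± 0.7` years, `followup_gap = 9.1` years, disorder
  duration uniform on 2–30 years (supporting short/long-duration splits).
* Clinical couplings: symptoms, hospitalisations and BMI load positively
  on disorder-pattern expression, verbal cognition negatively, and
  antipsychotic dose-years on the aging pattern; binary outcomes
  (remission, recovery, medication-free) follow a logistic link with low
  expression favouring good outcomes (base rate ≈ 25–30 %). Gaussian
  coupling noise defaults give R² ≈ 0.25 per variable.

`true_expression` (the planted per-observation disorder amplitude) is
stored in the phenotype table, and the full ground truth (baseline map,
pattern masks) is written alongside every dataset, enabling
parameter-recovery tests at every stage.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: anatomy and registration error,
partial-volume effects, spatially autocorrelated noise and scanner noise
spectra, non-linear aging, site-by-tissue interactions, missing-data
mechanisms, and diagnostic heterogeneity. Results on synthetic cohorts
validate the *implementation*, not clinical effect sizes.

## Numerical choices and degenerate inputs

* σ floor 1e-6 in z-normalization; CV-ratio cap ±1e6 at zero SE;
  zero-variance voxels yield NA in interaction maps and are excluded.
* Min–max never clips; constant features map to 0 and contribute nothing
  to back-projections.
* Degenerate inner folds (a single class) are skipped with a warning; an
  outer partition in which *all* folds are degenerate is an error.
* Outlier boundary is strict (a value exactly at mean + 3 SD is kept).
* Fisher's test uses the exact hypergeometric; Mann–Whitney reports the
  rank-sum W.
* All disk I/O is float32 (NIfTI-1 convention); computation is float64.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs.

## Problem sizes

Unit tests run on 4³–8³ grids with tens of subjects. The acceptance
pipeline (`scripts/acceptance.R`) and the heavier test blocks use the
package's chosen desk-scale study: an 8×8×8 grid, 70 + 74 discovery
subjects, a 29 + 61 longitudinal cohort, 561 brain-age training subjects,
3×3-fold outer / 3×2-fold inner CV, 500-permutation voxelwise FWE, and
5,000-permutation prognostic tests. Calibration suites use 200–500
simulated null datasets. These sizes were picked so the full pipeline
runs in minutes on one CPU while every statistical property remains
testable.

## Known limitations

* Only linear kernels; no probability calibration; no nonlinear
  registration or segmentation (upstream territory).
* The mixed-model R² variant and the CV-ratio denominator in the source
  methodology are ambiguous; both implemented readings are documented
  above and the alternative is one flag away.
* Detrending is linear only; alternative brain-age bias corrections
  (scaling approaches, quantile methods) are out of scope.
* The paired sign-flip scheme assumes symmetric errors in difference
  images; heavy-tailed noise would call for label permutation instead.
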