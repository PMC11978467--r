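---
title: "How the definition of post-SRS progression shapes a radiomic classifier's measured performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the definition of post-SRS progression shapes a radiomic classifier's measured performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After stereotactic radiosurgery (SRS), each treated brain metastasis (BM) is
followed with serial MRI and eventually called *progressing*, *stable* or
*regressing*. Studies that train machine-learning models to predict this
outcome from the pre-treatment scan disagree on what "progression" means:
how long the lesion is followed, which size-change criterion fires the call,
and whether treatment-related size changes (TRSCs) — pseudo-progression and
radiation necrosis — count as treatment failure. Because the definition
changes the ground-truth labels, it changes the measured performance of any
classifier trained on them. `srsprog` implements the full apparatus needed to
measure that sensitivity: a labelling engine over a grid of definitions, a
radiomic feature-extraction stage, a bootstrap out-of-bag evaluation harness,
and a synthetic cohort generator so everything is testable without clinical
data.

## The labelling model

A lesion's record is its pre-treatment baseline (three orthogonal diameters
in mm and a RANO-BM nodal diameter) plus follow-up measurements at known
months post-treatment. A *progression definition* is a triple:

* **Follow-up window** `w` ∈ {9, 12, 15, 18, 24} months; only scans strictly
  before `w` participate (the bound is exclusive).
* **Size-change metric.** Volume metrics estimate the volume as the product
  of the three orthogonal diameters (follow-up scans carry measurements, not
  contours) and fire when any in-window scan satisfies
  `V ≥ V0 (1 + p/100)` for `p` ∈ {10, 15, 20, 25} **and** `V − V0 ≥ 27 mm³`.
  The absolute floor is the RANO-BM 3 mm minimum diameter change applied in
  three dimensions; it guards small lesions against measurement noise and
  only binds for them. The RANO-BM metric fires at a ≥ 20% nodal-diameter
  increase, additionally requiring ≥ 3 mm absolute when the baseline is
  under 10 mm; scans whose nodal diameter is unmeasurable (cystic
  appearance) are skipped, and a lesion without a measurable baseline is an
  error, mirroring the usual cohort exclusion.
* **TRSC scheme.** A lesion that met the size criterion but is annotated PP
  or RN counts as progression only under schemes that include its
  annotation (`TRUE_ONLY`, `TRUE_PLUS_RN`, `TRUE_PLUS_PP`,
  `TRUE_PLUS_RN_PP`). Annotations are clinician-supplied inputs; the package
  never infers them from images.

Thresholds are read inclusively (`≥`): the primary sources describing these
criteria print both "≥" and ">" in different places, and the inclusive
reading is pinned by boundary tests so the behaviour is unambiguous.

Non-progressors are split by the *last* in-window scan: regressing if it
mirrors the progression rule downward (volume ≤ `V0 (1 − p/100)` with
≥ 27 mm³ absolute change; RANO diameter ≤ 70% of baseline, the
partial-response convention), else stable. The sources leave this boundary
unstated; the mirrored rule is a convention and only affects label-count
tables and the alternate task below, never who counts as progressing. A
lesion with no in-window follow-up defaults to stable (conservative
non-progression); `empty_followup = "exclude"` drops it instead.

Two task modes map the three-way label onto the binary outcome:
`PROG_VS_REST` (failure = progressing, the main task) and
`PROG_AND_STABLE_VS_REGRESS` (failure = progressing or stable, an alternate
contrast of limited clinical relevance that some studies report).

The default grid (`build_default_grid()`) holds two elements at the anchor
(window < 24, ≥ 25% volume, true progression only) while varying the third:
5 windows + 5 metrics + 4 schemes = 14 rows over 12 unique cells; the anchor
is computed once and reported in all three categories.

## The evaluation harness

Each experiment repeats, for `n_iterations` (default 250) bootstrap
iterations:

1. **Split.** Patients are sampled with replacement as many times as there
   are patients; the training multiset is their lesions (with multiplicity)
   and the never-sampled patients' lesions form the test set. The
   patient-level unit prevents within-patient leakage between train and
   test; a lesion-level unit is available as a switch
   (`unit = "lesion"`), since either is consistent with a mean held-out
   fraction of about 36% — the out-of-bag share `(1 − 1/P)^P → e^{−1}`.
2. **Filter.** Pearson correlations are computed on the training rows only;
   features are scanned in fixed column order and kept iff |r| ≤ 0.8
   against every already-kept feature. Zero-variance features are dropped
   first (their correlation is undefined). Greedy keep-first is the
   package's choice; only the cutoff is prescribed.
3. **Tune.** Tree count (10–1000, log scale) and depth (1 to the training
   size, so the model never has more levels than data) are chosen by
   maximising an inner 5-fold cross-validated AUC with a small Gaussian
   process surrogate: a Latin hypercube initial design, then
   expected-improvement proposals over a random candidate pool, falling back
   to random search when the surrogate is numerically singular. The budget
   (default 25 evaluations) and the objective are the package's choices; the
   search ranges and optimiser family are the method's.
4. **Fit and score.** A probability random forest (`ranger`) is fitted on
   the training multiset. The operating point is the threshold maximising
   Youden's J on the *training* ROC (ties toward higher specificity) so test
   sensitivity/specificity are not cherry-picked from the test curve. Test
   metrics are the rank-based AUC, the step-integrated AU-PRC (with the
   baseline AU-PRC equal to the positive prevalence), and
   sensitivity/specificity at the training threshold.

Per-metric means are reported with normal-approximation 95% CIs
(`mean ± 1.96·SD/√n`); the CI construction is the package's choice.
Degenerate splits (a class missing from either partition) are redrawn with a
fresh derived seed and counted. Seeding is counter-based — master seed →
per-iteration seeds — so any iteration is independently replayable, and
whole runs are pure functions of (inputs, config, seed).

**Importance.** Each iteration records permutation importances for the
retained features; filtered features score exactly zero; the retained scores
are min-max normalised to [0, 1] per iteration, averaged over iterations,
and the average min-max normalised again. A constant aggregate renormalises
to all zeros (documented edge case). Pooled subgroup metrics (e.g. lung vs
other primary site) gather all test-set probabilities over all iterations
and compute metrics per group on the pooled set — the route used when a
subgroup is too small to train on.

## The radiomic stage

`features_from_image()` runs: trilinear resampling to 0.5 mm isotropic
voxels (nearest-neighbour for masks — standard for intensity vs label
volumes), z-score normalisation using the mean and SD of brain voxels
*excluding* the lesion, clipped to ±3 SD, and extraction of 107 features at
a fixed count of 64 gray-level bins over the lesion's intensity range.
"At three standard deviations" admits several readings (clip inputs, clip
outputs, trim the statistics); clipping the normalised output at ±3 is
used here because it standardises the range without changing ranks within
[−3, 3].

The 107-feature set is the standard all-class composition: 14 shape, 18
first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features,
computed in 3D. GLCM and GLRLM counts are merged (summed) over the 13
unique directions before normalisation; zone/dependence/neighbourhood
families use 26-connectivity. Surface area and mesh volume come from a
marching-tetrahedra triangulation of the mask at iso-level 0.5; the binary
indicator is smoothed with one pass of a separable [1,2,1]/4 kernel before
meshing, which leaves flat boundaries exactly midway between voxel centres
but removes the staircase facets that would otherwise inflate the area of
oblique surfaces (a digital sphere's sphericity evaluates to ≈ 0.99 instead
of ≈ 0.78 on the raw voxel mesh; the mesh volume sits within a few percent
of the voxel volume). Axis lengths derive from the principal components of
the voxel-centre cloud; maximum diameters from boundary-voxel pairwise
distances.

## The synthetic cohort generator

The generator stands in for a single-centre SRS cohort followed for up to
two years; it exists so that every downstream stage has inputs with known
ground truth, not to imitate MRI appearance.

* **Trajectory classes.** Noiseless volume kernel
  `V(t) = V0 · exp(g·t_eff) · (1 + bump(t))`. True progressors grow
  exponentially from month 0 (default `g = ln 2 / 6`, a six-month doubling);
  late progressors are flat until a configurable onset (default month 12) —
  included so the follow-up-window sensitivity is exercisable; stable
  lesions are flat; regressors shrink (default six-month halving).
  Pseudo-progression carries a raised-cosine pulse with onset uniform in
  [3, 6] months that is exactly zero again at onset + 6 (the transient,
  self-resolving phenomenon); radiation necrosis carries a saturating,
  non-resolving bump with onset ≥ 6 months. Exponential-plus-relative-bump
  is the simplest monotone kernel that makes every threshold analytically
  checkable; no dynamical claim is intended.
* **Geometry and noise.** Each lesion draws a fixed axis-ratio triple with
  product 1, so the three orthogonal diameters are `r_i · V(t)^{1/3}` and
  their product equals the kernel volume *exactly* when noise is off — the
  volume-proxy rules are exact in the noiseless limit by construction.
  Every diameter at every timepoint (baseline included) carries independent
  multiplicative log-normal noise, default CV 5%; the RANO diameter is the
  largest orthogonal diameter with its own noise draw. Baseline sizes are
  log-normal (median 6.2 mm geometric-mean diameter, sdlog 0.45), chosen to
  match a published cohort's median volume of ~240 mm³ and its 13–14905 mm³
  range under the product proxy; the primary-site mix (lung 88/115) comes
  from the same cohort description. Class prevalences are **not** published
  for that cohort; the defaults (true 0.15, late 0.10, stable 0.35,
  regressor 0.25, PP 0.08, RN 0.07) are package defaults claimed as no
  study's data, and everything is configurable.
* **Feature tables.** `simulate_features()` produces Gaussian columns with
  a controlled number of informative features (class-conditional mean shift
  `d`, unit variance — the best single-feature AUC is `Φ(d/√2)`, which the
  tests verify empirically) and optional block correlation through a shared
  latent factor, giving the correlation filter realistic work.
* **Images.** `simulate_lesion_image()` renders an ellipsoidal lesion with
  tunable internal texture inside a spherical brain — just enough structure
  to exercise resampling, normalisation and all seven feature families.

What the generator does *not* emulate: real lesion morphology, scanner
effects, reader variability correlated across timepoints, informative
censoring (death before follow-up), or any coupling between image texture
and outcome beyond the planted statistical signal. Passing tests therefore
demonstrate the *pipeline's* correctness and the *direction* of
definition-sensitivity effects, not clinical performance levels.

## Numerical choices and problem sizes

* Window bounds strict; thresholds inclusive; ties at the operating point
  break toward specificity; AUC ties are averaged.
* Per-iteration importances are normalised over retained features only, so
  filtered features are exactly 0 rather than inheriting a shifted minimum.
* The test suite runs at deliberately reduced scale: grid runs use ~30
  patients and 3–8 iterations; the signal-recovery calibration uses 2000
  lesions, 50 iterations and a fixed forest (300 trees, depth cap 5, no
  per-iteration tuning) — with a single informative feature the tuned
  search concentrates on shallow trees anyway, and the fixed configuration
  reaches the same `Φ(d/√2)` ceiling at a fraction of the cost. The
  window-trend check uses 250 patients and 40 iterations. Full-scale runs
  (250 iterations, budget-25 tuning) use the same code paths with the
  default arguments.
* All randomness flows from explicit integer seeds; package functions never
  disturb the caller's RNG state.

## Worked example

```{r example}
library(srsprog)

cohort <- generate_cohort(cohort_config(n_patients = 62, n_lesions = 115,
                                        seed = 1))
truth <- cohort$lesions$true_class %in% c("true_progressor",
                                          "late_progressor")
features <- simulate_features(truth,
                              feature_table_config(n_informative = 10,
                                                   effect_size_d = 1.2,
                                                   block_size = 4,
                                                   within_block_rho = 0.5,
                                                   seed = 2),
                              lesion_id = cohort$lesions$lesion_id)

sens <- run_grid(cohort, features, seed = 3, n_iterations = 50,
                 tune_budget = 5, tune_folds = 3)
glance(sens)           # cross-definition AUC ranges per category
tidy(sens)             # long per-definition metric table
autoplot(sens)         # AUC point-range figure
plot_importance_heatmap(sens)
```

## Limitations

* The labelling engine adjudicates from measurements and annotations; it
  cannot detect TRSCs radiographically.
* The regression/stable boundary is a convention (see above).
* The grid treats definitions independently; it does not model correlations
  between definition elements a centre might impose jointly.
* Absolute metric values on synthetic cohorts say nothing about clinical
  cohorts; only the machinery and the qualitative sensitivities transfer.
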