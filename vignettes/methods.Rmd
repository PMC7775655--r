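---
title: "Methods: an MRI radiomics pipeline for predicting regrowth of pituitary macroadenomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MRI radiomics pipeline for predicting regrowth of pituitary macroadenomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A substantial fraction of non-functioning pituitary macroadenomas (NFPAs)
regrow after surgical resection.  Progression/recurrence (P/R) is defined
clinically as an increase of **more than 2 mm in at least one dimension**
of the residual tumor between postoperative MRI examinations; resection is
gross-total (GTR) when the residual volume is **below 10%** of the
original, subtotal (STR) otherwise.  This package implements a complete
radiomics analysis over two co-registered MRI contrasts — contrast-enhanced
T1-weighted (T1CE) and T2-weighted (T2) — that produces a per-patient
continuous risk score for P/R and feeds it into survival modelling.

The pipeline stages, each an exported function, are:

1. **Phantom cohort simulation** (`generate_phantom()`, `generate_cohort()`)
2. **Segmentation** (`resample_isotropic()`, `normalize_roi()`,
   `fcm_segment()`, `postprocess_mask()`, `transfer_mask()`,
   `erode_shell()`)
3. **Feature extraction** — 107 features per modality, 214 per case
   (`extract_all()`)
4. **Feature selection and scoring** (`sequential_select()`, `train_svm()`,
   `svm_score()`, `roc_analysis()`, `confusion()`)
5. **Outcome statistics** (`compare_groups()`, `km_logrank()`, `cox_fit()`)

`run_pipeline()` orchestrates all stages into a reproducible run
directory.

## Synthetic cohorts: what they emulate and what they do not

No patient images are distributed, so every stage is exercised on
simulated phantoms.  A phantom is an ellipsoidal "tumor" embedded in a
noisy background on an anisotropic grid (default 64×64×32 voxels at
1×1×1.5 mm).  The background carries i.i.d. Gaussian noise (SD 1); tumor
voxels carry a class contrast (default 3 SD on T1CE — an enhancing lesion
against background, 2.4 SD on T2) plus a *correlated* Gaussian texture
field.  The texture field is white noise smoothed with a Gaussian kernel
of width `texture_granularity_mm` and rescaled to `heterogeneity_sd`; a
single parameter thus controls spatial coarseness, and NGTDM coarseness
responds monotonically to it (a tested property).

Cohort defaults encode the study conditions the analysis assumes:

* 50 cases with **exactly** `round(n × 0.56) = 28` P/R cases.  Class
  counts are fixed rather than Bernoulli-drawn so the target prevalence
  holds for every seed; prevalence is a design parameter of the cohort,
  not an estimated quantity.
* Maximum tumor height lognormal with median 35.5 mm (IQR ≈ 27.5–43.5) in
  the P/R class versus 18 mm (IQR ≈ 10–26) in the stable class, truncated
  by rejection to [11, 58] mm so tumors fit the grid; the truncation
  shifts the class medians by at most ~2 mm, which is why the
  median-recovery test uses a ±2.5 mm band.
* Coarser texture in the P/R class (granularity ≈ 3 mm vs ≈ 1.2 mm,
  higher heterogeneity).  The underlying study does not quantify texture
  differences between classes; these effect sizes are free simulation
  parameters, not claims about real cohorts.
* Survival: event times are exponential (Weibull shape 1, a deliberate
  default with closed-form checks) with log-hazard linear in the latent
  severity; follow-up is lognormal with median 38 months clamped to
  [12, 115].  For P/R cases the event time is drawn **conditional on
  preceding the follow-up time** (inverse-CDF truncation), so the P/R
  label, the event flag and the censoring status are mutually consistent,
  and the recorded follow-up dimensions grow by >2 mm on at least one
  axis for events and by at most 2 mm for non-events — the progression
  rule is exactly testable on every generated case.
* Clinical covariates (sex, visual disturbance, hypopituitarism grade,
  resection extent, cavernous-sinus and extrasellar grade groups,
  compressions, …) are drawn with class-conditional frequencies matching
  the cohort table the analysis targets.

Phantoms deliberately omit realistic pituitary anatomy, cavernous-sinus
geometry, bias fields, and scanner artifacts.  Passing tests therefore
demonstrate the *correctness of the computational chain* under known
ground truth, not clinical performance on real MRI.

## Segmentation chain

Volumes are resampled to isotropic spacing (default: the minimum input
spacing, so no axis is downsampled) with trilinear interpolation, then
z-normalized (mean 0, SD 1) over the operator ROI.  Normalization uses the
**population** (n-denominator) SD — a fixed, tested convention.
Resampling precedes normalization.

Slice-wise fuzzy c-means (FCM) clusters the in-rectangle intensities of
each slice into k = 2 fuzzy clusters (fuzzifier m = 2, absolute objective
tolerance 1e-5, ≤ 300 iterations, k-means++-style seeded initialization).
The lesion cluster is the one with the **higher center** — on T1CE the
tumor enhances.  The FCM objective is non-increasing across iterations
(asserted in tests) and the implementation is cross-checked against
`e1071::cmeans` on shared inputs.

Cleanup keeps the largest **face-connected (6-neighbourhood)** 3D
component and then fills holes (2D per slice, then 3D).  Face connectivity
was chosen over vertex (26) connectivity for the component step after a
percolation analysis: at the phantom's noise level ~7% of background
voxels exceed the FCM membership boundary, which is above the ~2.4% site
percolation threshold of the 26-neighbourhood lattice but far below the
~31% threshold of the 6-neighbourhood lattice — with 26-connectivity,
salt noise chains itself onto the lesion through diagonal contacts and
inflates the mask, which is visible as a Dice drop from ~0.96 to ~0.73.
Scattered-voxel removal is the stated purpose of this step, and diagonal
chains are exactly scattered voxels.

Masks transfer between contrasts by affine transformation of the mask as
a continuous field with trilinear interpolation, binarized at 0.5 (the
natural midpoint; identity transforms reproduce the input exactly).

Boundary shells of 0.25 and 0.5 cm are removed by **per-slice 2D binary
erosion** implemented as an exact, spacing-aware Euclidean distance
transform threshold: a pixel survives when its in-plane distance to the
nearest background pixel exceeds the depth.  Physical distance (mm) is
used rather than a fixed pixel count, because the depths are stated as
lengths.  Note that slice-wise erosion retains more volume near the
poles of a round lesion than 3D erosion would; the analytic oracle for
the eroded sphere is therefore the stack of eroded disks, not a smaller
sphere.  Erosion variants nest: eroded(0.5) ⊆ eroded(0.25) ⊆ original.

## The feature bank

Each case yields 214 named features — per modality: 18 first-order, 14
shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM (107 = 32
first-order + shape and 75 textural).  Names follow the widely used
radiomics naming convention (`T1_glcm_Imc1`, `T2_ngtdm_Coarseness`, …) so
cross-implementation comparison is mechanical.  No filtered images
(wavelet, LoG) are used.

Key numerical conventions, all tested:

* Intensities are ROI z-normalized, then discretized into a **fixed bin
  count of 32** equal-width levels (min → level 1, max → level 32).
  Every feature is therefore invariant under affine intensity rescaling.
* GLCM: distance 1, 13 unique 3D directions, symmetric and normalized per
  direction; features computed per direction and averaged.  IMC1 =
  (HXY − HXY1)/max(HX, HY), defined as 0 on a constant ROI.  Correlation
  on a constant ROI is 1; MCC is 1 when fewer than two levels are active.
* NGTDM over in-mask 26-neighbourhoods; coarseness = 1/Σᵢ pᵢ sᵢ with a
  documented sentinel of 1e6 for uniform ROIs.
* GLRLM runs along the 13 directions (averaged); GLSZM zones are
  26-connected equal-level components; GLDM dependence counts equal-level
  neighbours (α = 0), with dependence size = count + 1.
* First-order: population moments; Kurtosis is the Pearson (non-excess)
  convention (normal reference 3); skewness/kurtosis of a constant ROI
  are defined as 0; percentiles use linear interpolation.
* Shape: surface area and mesh volume come from a marching-tetrahedra
  triangulation of an implicit field (the binary mask smoothed with a
  Gaussian of σ = 0.7 voxels, minus ½).  The smoothing width balances
  sub-voxel surface placement on curved boundaries against corner
  rounding on flat faces: both a digitized 10 mm sphere and a 20 mm cube
  reproduce their analytic surface-to-volume ratios (3/r and 6/a) within
  5%.  Mesh volume comes from the divergence theorem over the oriented
  triangles.  Axis lengths are 4√λ from PCA of the physical voxel
  coordinates; maximum diameters are largest pairwise boundary-voxel
  distances (per plane for the 2D variants).

Verification is dual-route: (i) on all small fixture ROIs (≤ 8×8×3) the
five texture matrices equal exhaustive brute-force enumerations written
as independent voxel-loop oracles in the test suite; (ii) over 30 varied
phantoms the 93 intensity/texture features per modality are compared
feature-by-feature (Pearson r ≥ 0.99) against a bundled, independently
written Python oracle (`inst/oracle/radiomics_oracle.py`, numpy/scipy)
that shares no code with the R implementation.  Shape features are
excluded from the cross-implementation route by design — meshing
algorithms differ legitimately between implementations — and are instead
validated against closed-form solids, which is the stronger check.

## Selection, SVM score, ROC

The feature-selection objective is the **mean misclassification rate**
of a Gaussian-kernel SVM under stratified 10-fold cross-validation,
repeated with re-randomized folds ("performance" is otherwise
underspecified; the misclassification rate is the conventional reading,
and the objective is configurable).  The kernel is exactly
`G(xₙ, x) = exp(−‖xₙ − x‖²)` — scale fixed at 1, as the score equation is
printed without a scale parameter — on features standardized **inside
each training fold only**; the box constraint is C = 1.  Both are exposed
as configuration.

Sequential forward selection starts from an empty set; at each step every
unselected feature is evaluated with the same fold randomization (paired
comparisons), the best is added, and selection stops when the improvement
falls below the termination tolerance 1e-6 or when `max_features` (3, the
depth of the published model) is reached.  The improvement is measured
against the current set *re-evaluated under the step's own folds*: with
a stale reference, a feature that changes nothing (for instance one made
constant by ROI normalization) can masquerade as an improvement through
fold noise alone.  Ties break toward the first
feature in canonical (sorted-name) order, for determinism.  The study
setting repeats the fold randomization 1000 times per evaluation; tests
and the acceptance script use reduced repeats (20 in the planted-signal
check, 3–5 elsewhere) with fixed seeds, trading objective-estimate
variance for runtime at our test problem sizes.

The per-case risk score is the explicit kernel expansion
f(x) = Σₙ wₙyₙ G(xₙ, x) + b evaluated from the stored support vectors;
tests require it to match the trained model's decision values to 1e-8.
The stored orientation makes higher scores indicate P/R.

ROC analysis predicts positive at score ≥ threshold, computes AUC by the
trapezoid rule (identical to the normalized Mann–Whitney U statistic, a
tested identity, and cross-checked against `pROC`), and returns the
cutoff maximizing the Youden index, ties broken toward higher
specificity.  Confusion tables use the closed-on-positive rule
(score ≥ cutoff).

## Outcome statistics

Group comparisons: categorical covariates use the chi-square test,
switching to Fisher's exact test when **any expected cell count is
below 5** (the conventional rule; with it, the visual-disturbance
contrast of 26/28 vs 13/22 reproduces the published p = 0.006);
continuous covariates use the two-sided Mann–Whitney U test and are
summarized as median (IQR).

Progression-free survival uses Kaplan–Meier estimates per group with the
two-sided log-rank test.  Cox proportional-hazards models (Efron tie
handling) run univariately per covariate; the multivariate model includes
exactly the covariates with univariate p < 0.05.  Continuous covariates
(age, height, volume, SVM score) enter untransformed, matching per-unit
hazard ratios.  Non-convergence or extreme coefficients are flagged in
the result rather than silently dropped.

## Problem sizes and determinism

Every stochastic component takes an explicit seed and is bit-reproducible
under it; `run_pipeline()` derives all stage seeds from one master seed
and embeds the configuration hash in every output.  The test-suite
problem sizes are: 20 phantom segmentations for the Dice check, 30
phantoms for the cross-implementation correlation, 20 seeded replicates
of the planted-signal selection (n = 100, 50 noise features, 10 CV
repeats; the 3 informative features are each class-shifted by 0.8 SD and
negatively correlated within class, ρ = −0.45, so each contributes a
large complementary gain — with independently shifted features the
conditional gain of the third feature is comparable to the chance
advantage of the best of 50 noise features at this sample size, and no
selection procedure can separate them reliably), 100 replicates of Cox
hazard-ratio recovery at n = 500, and 200 replicates for null
calibrations.  The acceptance script runs the full pipeline on one
50-case cohort with all three ROI variants.

## Known limitations

* Phantoms are ellipsoids with stationary texture; none of the
  irregular-margin, cystic or hemorrhagic appearances of real NFPAs are
  modelled, and segmentation Dice on phantoms should not be read as
  clinical accuracy.
* The cohort-level discriminative results (AUC, cutoff, hazard ratios)
  depend on the free class-separation parameters of the simulator; they
  demonstrate that the chain detects planted signal, not that the
  published patient-level numbers are reproduced — those require the
  original cohort, which is not available.
* The FCM surrogate for the operator's initialization uses the truth
  bounding box; a human operator would draw it, and gross over/under
  segmentation would be manually corrected, which is not modelled.
* Manual mask correction is replaced by a mask-override hook: any mask
  file can be substituted before feature extraction.
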