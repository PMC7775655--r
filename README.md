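# pitradiomics

An R implementation of an end-to-end MRI radiomics analysis for
predicting progression/recurrence (P/R) of non-functioning pituitary
macroadenomas (NFPAs) from two MRI contrasts: contrast-enhanced
T1-weighted (T1CE) and T2-weighted (T2) volumes.

About a quarter to a half of NFPAs regrow after surgery (P/R: a > 2 mm
increase of the residual tumor in at least one dimension).  The analysis
builds a continuous per-patient risk score from quantitative image
features and relates it to progression-free survival.  The pipeline:

1. **Phantom simulation** — two-channel tumor phantoms and full cohorts
   with class-conditional size/texture distributions, censored follow-up
   and clinical covariates, so every stage is testable without patient
   data.
2. **Segmentation** — isotropic resampling, ROI z-normalization,
   slice-wise fuzzy c-means (k = 2, m = 2) on T1CE, largest-component and
   hole-filling cleanup, affine mask transfer to T2, and per-slice
   boundary erosion (0.25 / 0.5 cm shells) for three ROI variants.
3. **Features** — 107 features per modality (18 first-order, 14 shape,
   24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM), 214 per case, with
   fixed 32-level discretization and 13-direction aggregation.
4. **Model** — sequential forward feature selection driven by the
   cross-validated misclassification rate of a Gaussian-kernel SVM
   (stratified 10-fold CV, repeated; termination tolerance 1e-6; model
   depth 3), and the explicit decision score

   f(x) = Σₙ wₙ yₙ exp(−‖xₙ − x‖²) + b

   followed by ROC analysis with a Youden-optimal cutoff and a
   TP/TN/FP/FN performance table per ROI variant.
5. **Outcomes** — chi-square / Fisher / Mann–Whitney group comparisons,
   Kaplan–Meier curves split at the score cutoff with the log-rank test,
   and univariate → multivariate (p < 0.05 promotion) Cox
   proportional-hazards models.

## Worked example

```r
library(pitradiomics)

# one phantom case
ph <- generate_phantom(phantom_spec(rng_seed = 7))
fv <- extract_all(ph$t1ce, ph$t2, ph$mask)
length(fv)                      # 214
fv["T1_shape_SurfaceVolumeRatio"]
#> T1_shape_SurfaceVolumeRatio
#>                   0.2418286

# full pipeline on a small synthetic cohort
cfg <- pipeline_config(out_dir = "scratch/demo_run", seed = 1,
                       cohort = cohort_spec(n_cases = 12,
                                            pr_prevalence = 0.5),
                       selection = list(repeats = 2, max_features = 2))
res <- run_pipeline(cfg)
#> Warning: case 10: erosion emptied the mask; case dropped
res$table3
#>      variant tp tn fp fn accuracy auc
#> 1   original  6  6  0  0        1   1
#> 2 eroded_025  6  6  0  0        1   1
#> 3  eroded_05  6  5  0  0        1   1
res$km$p
#> [1] 0.0007318153
```

At this toy size the planted class separation is large, so the
out-of-fold confusion table is perfect (12 cases, accuracy 1.0) and the
high-score group progresses significantly earlier (log-rank p ≈ 7e-4);
one small tumor is dropped from the 0.5 cm erosion variant because the
shell removal empties its mask — the behaviour the erosion errors
prescribe.  `res$table3` is the per-ROI-variant performance table
(counts, accuracy, AUC of the out-of-fold SVM scores); `res$km$p` is the
log-rank p-value of progression-free survival split at the ROC-optimal
score cutoff, and `res$cox` the univariate Cox table.  The run directory contains the
masks (NIfTI), per-variant feature and score CSVs, the model JSON
(support vectors, weights, bias, standardization) and report tables, all
stamped with the seed and config hash.

The numbered scripts under `analysis/` run the same stages as a
step-by-step narrative workflow (simulate → segment → extract → select /
score → outcome statistics), writing tables under `results/`.

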