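Package: pitradiomics
Title: MRI Radiomics Pipeline for Predicting Regrowth of Pituitary Macroadenomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements an end-to-end radiomics analysis for non-functioning
    pituitary macroadenomas imaged with contrast-enhanced T1-weighted and
    T2-weighted MRI: phantom cohort simulation, fuzzy c-means tumor
    segmentation with morphological cleanup and boundary-erosion ROI
    variants, a 107-feature-per-modality bank (first-order, shape, GLCM,
    GLRLM, GLSZM, NGTDM, GLDM), sequential forward feature selection driven
    by a Gaussian-kernel support-vector-machine objective under repeated
    stratified cross-validation, an SVM risk score with ROC/optimal-cutoff
    analysis, and progression-free-survival modelling by Kaplan-Meier,
    log-rank and Cox proportional hazards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
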