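Package: vsgrowth
Title: Predicting Vestibular Schwannoma Growth from Structural and
    DCE-MRI Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for predicting vestibular
    schwannoma growth under wait-and-scan management from structural
    T2-weighted MRI and dynamic contrast-enhanced (DCE) MRI. Includes
    extended Tofts model simulation and voxelwise fitting (Ktrans, ve, vp),
    region-of-interest conditioning (Z-score normalization, cyst removal,
    cross-shaped erosion, mask projection), volume-dependent growth
    labeling on consecutive follow-up scans, an IBSI-style radiomic
    feature engine (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM;
    101 features per channel across four channels), a nested stratified
    cross-validated F-test/PCA/SVM classifier with per-fold Youden
    cutoffs, and discrimination, calibration, decision-curve and
    feature-importance analytics. A seeded synthetic cohort generator
    emulating the study's data structure makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
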