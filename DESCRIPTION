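Package: petrad
Title: FDG-PET Standard Uptake Value Segmentation and Radiomics Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processing and classification pipeline for whole-body FDG-PET
    activity volumes. Converts activity images to standard uptake values (SUV),
    resamples to an isotropic grid, smooths and thresholds to a high-uptake mask,
    partitions the mask into candidate tissue regions with a marker-based
    watershed, computes first-order, shape and texture (GLCM/GLRLM) radiomics
    features per region, and classifies regions as brain, heart, left/right
    kidney, bladder or tumor with a random forest under a per-scan
    sole-occurrence constraint. Includes segmentation and concordance evaluation
    metrics and a synthetic whole-body phantom generator with ground-truth
    labels so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
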