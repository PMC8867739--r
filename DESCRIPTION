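Package: bmpet
Title: Bone Marrow FDG-PET/CT Quantification with Digital Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automated quantification of skeletal bone-marrow glucose
    metabolism from paired FDG-PET/CT volumes. Segments the spine and pelvic
    marrow cavity from CT by Hounsfield thresholding, morphological closing
    and slice-wise cortex erosion, masks the PET volume, converts voxel
    values to lean-body-mass-normalized uptake (SUL), and computes
    first-order histogram features (SUL max, SUL mean, Shannon entropy),
    the percentage of marrow volume above the mediastinal reference, and a
    Deauville-style reference-region score for the eleventh thoracic
    vertebra. Ships a parametric torso phantom and cohort simulator with
    exact ground-truth masks, reproducibility metrics (intersection over
    union, intraclass correlation), and the cohort statistics layer
    (t and Mann-Whitney tests, Pearson and Spearman correlation,
    multivariate regression, one-way ANOVA, chi-square and Fisher tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
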