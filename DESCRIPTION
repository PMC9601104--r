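Package: radrobust
Title: Robustness of Delta-Radiomic Outcome Models to Tumour Segmentation Accuracy
Version: 0.1.0
Authors@R:
    person("radrobust", "maintainers", email = "maintainers@radrobust.org",
           role = c("aut", "cre"))
Description: Tools to quantify how tumour-segmentation accuracy affects
    MRI delta-radiomic biomarkers of radiotherapy outcome in brain
    metastasis. Provides a seeded synthetic-cohort generator (paired
    baseline/follow-up two-channel volumes with outcome-linked growth,
    texture change and survival), segmentation quality metrics (Dice,
    Hausdorff, volume estimation error) with controlled mask degradation
    to prescribed Dice targets, a cascaded segmentation orchestrator with
    pluggable backends, a full radiomic feature extractor (first-order,
    2D/3D shape, GLCM/GLRLM/GLSZM/NGTDM/GLDM, stationary wavelet
    sub-bands, tumour plus 5 mm margin, delta features), minimum
    redundancy maximum relevance feature selection with the quotient
    criterion, a class-weighted Gaussian-kernel support vector machine,
    Kaplan-Meier/log-rank survival stratification, and an experiment
    driver that measures feature and model degradation across
    segmentation quality levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
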