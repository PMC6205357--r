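Package: lesionmapr
Title: Lesion-Symptom Mapping and Cross-Validated Lesion-Load Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-based lesion-symptom mapping (VLSM) with
    permutation-based continuous (generalized) family-wise error control, a
    sparse multivariate lesion-symptom mapping routine in the SCCAN family
    with cross-validated sparseness optimization, direct total lesion volume
    control (dTLVC) normalization, PCA with varimax rotation for behavioral
    batteries, and an 8-fold cross-validated pipeline that quantifies the
    predictive contribution of lesion location (template lesion load) beyond
    lesion size via nested regression. Includes a synthetic stroke-lesion
    cohort generator (stochastic region growing over a vascular-territory
    probability field) with planted critical regions and factor structure,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
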