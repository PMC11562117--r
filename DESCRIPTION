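Package: texd50
Title: Voxel-Wise MRI Texture Mapping and D50 Disease-Progression Modelling for ALS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pseudo-longitudinal analysis of T1-weighted brain MRI in
    amyotrophic lateral sclerosis (ALS). Fits the sigmoidal D50 disease-progression
    model to ALSFRS-R score series and derives disease accumulation (rD50, phase)
    and aggressiveness (D50 class) descriptors; computes voxel-wise grey-level
    co-occurrence matrix (GLCM) autocorrelation texture maps on three orthogonal
    planes; runs mass-univariate general linear models with nuisance covariates and
    cluster-extent thresholding; produces cohort demographic summaries with
    normality-gated group tests; and generates seeded synthetic cohorts and 3D
    texture phantoms so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
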