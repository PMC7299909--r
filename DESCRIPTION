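Package: amystage
Title: Reference-Free Staging and Quantification of Amyloid PET Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Machine-learning staging of amyloid PET scans without a reference
    region. Selects the axial assessment slices a visual rater would use from a
    co-registered parcellation volume, extracts grey-to-white uptake-curve
    features with a geodesic distance transform, predicts continuous regional
    cortical tracer uptake (pRCTU) with per-region support-vector regression,
    and assigns a three-level amyloid stage hierarchically: a linear SVM on the
    eight-region pRCTU vector decides cortical positivity, then PCA plus linear
    discriminant analysis on striatal pixel intensities decides striatal
    positivity. Includes discriminative-pattern extraction from the fitted
    linear models, SUVr computation with the iterative-outlier positivity
    cutoff, covariate-adjusted stage comparisons with Bonferroni correction and
    linear trend contrasts, pRCTU outcome regressions, bootstrap mediation path
    analysis, and a synthetic brain-phantom cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    e1071,
    MASS,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
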