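Package: emmfuse
Title: Fusion of Electromechanical Maps with MRI-Derived Left-Ventricular Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers catheter-based electromechanical mapping (EMM) point
    clouds onto a left-ventricular endocardial surface mesh built from
    short-axis cine-MRI contours, and relates the mapped electrical and
    mechanical parameters (unipolar/bipolar voltage, linear local shortening)
    to late-gadolinium-enhancement infarct transmurality. Provides mesh
    construction from stacked contours, apex-initialized rotation-constrained
    iterative-closest-point registration, area-based infarct-transmurality
    bullseye computation, wall thickening, ROC-grid threshold optimization,
    random-intercept mixed-model variance explained, and a fully synthetic
    infarcted-ventricle phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
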