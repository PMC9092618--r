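Package: aromaQSPR
Title: QSPR Modeling of Odor Thresholds with GFA Variable Selection and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete quantitative structure-property relationship (QSPR)
    workflow for odor-threshold modeling of wine aroma compounds: curation and
    merging of literature odor-threshold records, molecular-descriptor
    pre-filtering (missing values, near-constant columns, pairwise
    correlation), rational train/test division by k-medoid (PAM) clustering,
    genetic function approximation (GFA) variable selection with truncated
    linear spline terms and Friedman lack-of-fit scoring, exhaustive
    best-subset multiple linear regression, NIPALS partial least squares with
    leave-one-out latent-variable selection, variable importance in projection
    (VIP), DModX and Hotelling T-squared applicability-domain diagnostics,
    Y-randomization, an external-validation battery (rm2 metrics, Q2F2,
    concordance correlation coefficient, Golbraikh-Tropsha and MAE-based
    criteria), and composite odor-threshold prediction for multi-component
    wines. Includes a synthetic-data generator emulating the statistical
    structure of descriptor matrices so the whole pipeline is testable without
    proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
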