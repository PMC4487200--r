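Package: intrinsicSSc
Title: Molecular Response Analysis for Intrinsic-Subset Stratified Systemic
    Sclerosis Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for placebo-controlled trials in diffuse
    cutaneous systemic sclerosis that pair skin gene-expression profiling with
    the modified Rodnan skin score (mRSS). Implements two-colour microarray
    preprocessing (missingness filtering, k-nearest-neighbour imputation,
    median centering, probe-to-gene collapse), nearest-centroid intrinsic
    subset classification by Spearman correlation against a labelled reference
    cohort, gene-signature trajectory scoring, two-class marker selection,
    gene-set enrichment (GSEA, single-sample GSEA, hypergeometric
    over-representation), and the clinical layer: last-observation-carried-
    forward, responder classification by relative mRSS change, exact
    small-sample tests, summary-statistic t tests, and a disease-duration-
    adjusted random-intercept mixed model for longitudinal mRSS. A synthetic
    randomized-trial simulator with known ground truth supports end-to-end
    validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
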