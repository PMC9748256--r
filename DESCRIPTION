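Package: localLR
Title: Calibration of Variant-Effect Predictors into ACMG/AMP Evidence
    Strengths via Local Positive Likelihood Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts continuous variant pathogenicity prediction scores into
    ACMG/AMP PP3/BP4 evidence strengths (supporting, moderate, strong, very
    strong, in both the pathogenic and benign directions). The calibration
    estimates a local positive likelihood ratio curve from labeled
    pathogenic/benign variants with an adaptive sliding window, applies
    prior-matching benign weighting, bounds the curve with one-sided bootstrap
    confidence limits, and selects score thresholds whose bounded evidence
    meets exponentially scaled likelihood-ratio cutoffs. Includes validation
    of thresholds on independent variant sets through interval-based
    likelihood ratios and population-fraction audits, a nonparametric
    positive-unlabeled estimator of the prior probability of pathogenicity,
    a variant-filtering engine for assembling calibration data sets from
    clinical and population variant tables, and a synthetic score generator
    with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
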