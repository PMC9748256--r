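#' @import methods
#' @importFrom stats quantile rbeta rnorm runif dbeta dnorm qnorm uniroot
#'   setNames aggregate
#' @importFrom utils read.delim write.table head tail
#' @useDynLib localLR, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Ordered ACMG/AMP evidence strengths used throughout the package.
.STRENGTHS <- c("supporting", "moderate", "strong", "very_strong")
.DIRECTIONS <- c("pathogenic", "benign")

#' EvidenceConfig: prior, scaling constant and per-strength cutoffs
#'
#' Holds the Bayesian evidence model configuration: the prior probability of
#' pathogenicity, the scaling constant `c` of the exponential evidence model
#' (a single very strong line of evidence corresponds to a positive likelihood
#' ratio of `c`, strong to `c^(1/2)`, moderate to `c^(1/4)` and supporting to
#' `c^(1/8)`), and the derived likelihood-ratio and posterior-probability
#' cutoffs for each strength in both the pathogenic (PP3) and benign (BP4)
#' directions.  Benign cutoffs are the exact reciprocals of the pathogenic
#' ones, and benign posterior cutoffs are expressed as probability of
#' benignity.
#'
#' Use [evidenceConfig()] or [strengthCutoffTable()] to construct objects.
#'
#' @slot prior numeric(1), prior probability of pathogenicity in (0, 1).
#' @slot c numeric(1), scaling constant, greater than 1.
#' @slot cutoffs data.frame with columns `criterion`, `strength`, `direction`,
#'   `lr_cutoff`, `lr_reciprocal` and `posterior_cutoff`.
#' @export
setClass("EvidenceConfig",
    representation(prior = "numeric", c = "numeric", cutoffs = "data.frame"))

setValidity("EvidenceConfig", function(object) {
    msg <- character()
    if (length(object@prior) != 1L || is.na(object@prior) ||
        object@prior <= 0 || object@prior >= 1)
        msg <- c(msg, "'prior' must be a single probability in (0, 1)")
    if (length(object@c) != 1L || is.na(object@c) || object@c <= 1)
        msg <- c(msg, "'c' must be a single value > 1")
    if (nrow(object@cutoffs) != 8L)
        msg <- c(msg, "'cutoffs' must have one row per strength and direction")
    if (nrow(object@cutoffs) == 8L) {
        path <- object@cutoffs[object@cutoffs$direction == "pathogenic", ]
        ben  <- object@cutoffs[object@cutoffs$direction == "benign", ]
        if (is.unsorted(path$lr_cutoff, strictly = TRUE))
            msg <- c(msg, "pathogenic lr cutoffs must strictly increase")
        if (!is.unsorted(ben$lr_cutoff, strictly = TRUE))
            msg <- c(msg, "benign lr cutoffs must strictly decrease")
        recip <- path$lr_cutoff * ben$lr_cutoff
        if (any(abs(recip - 1) > 1e-9))
            msg <- c(msg, "benign lr cutoffs must be reciprocals of pathogenic ones")
        if (is.unsorted(path$posterior_cutoff, strictly = TRUE) ||
            is.unsorted(ben$posterior_cutoff, strictly = TRUE))
            msg <- c(msg, "posterior cutoffs must strictly increase with strength")
    }
    if (length(msg)) msg else TRUE
})

#' ScoreSet: per-variant prediction scores for one tool
#'
#' A container for the raw scores one computational tool assigns to a set of
#' variants.  Scores may be missing (`NA`); each variant key appears at most
#' once.  The `orientation` records whether higher or lower scores indicate
#' pathogenicity on the tool's native scale; [normalizeOrientation()] maps
#' every tool onto the higher-is-pathogenic convention (by negation) and the
#' `flipped` flag lets thresholds be reported back on the native scale.
#'
#' @slot toolName character(1) identifier of the tool.
#' @slot variantKey character vector of unique variant identifiers.
#' @slot score numeric vector of scores (NA allowed), parallel to `variantKey`.
#' @slot orientation `"higher"` or `"lower"` (is pathogenic).
#' @slot flipped logical(1); `TRUE` once a lower-is-pathogenic tool has been
#'   normalized by negation.
#' @export
setClass("ScoreSet",
    representation(toolName = "character", variantKey = "character",
                   score = "numeric", orientation = "character",
                   flipped = "logical"))

setValidity("ScoreSet", function(object) {
    msg <- character()
    if (length(object@variantKey) != length(object@score))
        msg <- c(msg, "'variantKey' and 'score' lengths differ")
    if (anyDuplicated(object@variantKey))
        msg <- c(msg, "variant keys must be unique")
    if (!object@orientation %in% c("higher", "lower"))
        msg <- c(msg, "'orientation' must be \"higher\" or \"lower\"")
    if (any(is.infinite(object@score), na.rm = TRUE))
        msg <- c(msg, "scores must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' CalibrationCurve: local posterior / local lr+ estimates with bounds
#'
#' The result of [calibrateScores()]: for every unique score of the labeled
#' calibration variants, the adaptive window half-width, the (resampled-free)
#' pathogenic and benign counts inside the window, the weighted local
#' posterior probability of pathogenicity, the corresponding local positive
#' likelihood ratio, and bootstrap quantiles of the posterior.  The one-sided
#' bounds are conservative: `boundPathogenic` (lower) never exceeds the point
#' estimate and `boundBenign` (upper) is never below it.
#'
#' @slot score sorted unique scores (normalized, higher-is-pathogenic scale).
#' @slot epsilon adaptive window half-width at each score.
#' @slot nPathogenic,nBenign raw (unweighted) class counts in each window.
#' @slot posterior weighted local posterior point estimate in `[0, 1]`.
#' @slot lrPlus local positive likelihood ratio point estimate (may be `Inf`
#'   for pure pathogenic windows).
#' @slot boundPathogenic one-sided lower bootstrap bound (posterior scale).
#' @slot boundBenign one-sided upper bootstrap bound (posterior scale).
#' @slot ciLower,ciUpper two-sided bootstrap quantiles (posterior scale),
#'   used when assessing fixed thresholds.
#' @slot prior prior probability used to convert posterior to lr+.
#' @slot weight benign weight `w` applied inside windows.
#' @slot nBoot number of bootstrap replicates behind the bounds.
#' @slot settings list of calibration settings (see [calibrationSettings()]).
#' @slot toolName tool identifier carried over from the [ScoreSet].
#' @slot flipped whether scores were negated during orientation normalization.
#' @export
setClass("CalibrationCurve",
    representation(score = "numeric", epsilon = "numeric",
                   nPathogenic = "numeric", nBenign = "numeric",
                   posterior = "numeric", lrPlus = "numeric",
                   boundPathogenic = "numeric", boundBenign = "numeric",
                   ciLower = "numeric", ciUpper = "numeric",
                   prior = "numeric", weight = "numeric", nBoot = "numeric",
                   settings = "list", toolName = "character",
                   flipped = "logical"))

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    n <- length(object@score)
    same <- c(length(object@epsilon), length(object@posterior),
              length(object@nPathogenic), length(object@nBenign))
    if (any(same != n))
        msg <- c(msg, "per-score slots must have equal length")
    if (is.unsorted(object@score, strictly = TRUE))
        msg <- c(msg, "'score' must be strictly increasing (unique scores)")
    if (any(object@posterior < -1e-12 | object@posterior > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "posterior estimates must lie in [0, 1]")
    if (length(object@boundPathogenic) == n && n > 0) {
        if (any(object@boundPathogenic > object@posterior + 1e-12))
            msg <- c(msg, "pathogenic-side bound must not exceed point estimate")
        if (any(object@boundBenign < object@posterior - 1e-12))
            msg <- c(msg, "benign-side bound must not fall below point estimate")
    }
    if (length(msg)) msg else TRUE
})

#' ThresholdSet: per-strength score thresholds in one direction
#'
#' Thresholds selected from a bounded [CalibrationCurve-class] for one direction of
#' evidence.  A strength whose cutoff is never met carries `NA` (rendered as
#' "-" in reports).  Pathogenic thresholds are nested
#' `tau_su <= tau_mo <= tau_st <= tau_vs`; benign thresholds are nested the
#' other way.  `nativeThreshold` reports the same thresholds on the tool's
#' native scale (undoing orientation normalization).
#'
#' @slot direction `"pathogenic"` or `"benign"`.
#' @slot threshold named numeric, normalized scale, `NA` when not met.
#' @slot nativeThreshold named numeric, native tool scale.
#' @slot lrCutoff named numeric, the lr+ cutoff each strength must satisfy.
#' @export
setClass("ThresholdSet",
    representation(direction = "character", threshold = "numeric",
                   nativeThreshold = "numeric", lrCutoff = "numeric"))

setValidity("ThresholdSet", function(object) {
    msg <- character()
    if (!object@direction %in% .DIRECTIONS)
        msg <- c(msg, "invalid direction")
    if (!identical(names(object@threshold), .STRENGTHS))
        msg <- c(msg, "'threshold' must be named supporting..very_strong")
    th <- object@threshold
    met <- !is.na(th)
    ## weaker strengths must be met before stronger ones
    if (any(diff(met) > 0))
        msg <- c(msg, "a strength is met while a weaker one is not")
    if (sum(met) > 1) {
        d <- diff(th[met])
        ok <- if (object@direction == "pathogenic") all(d >= 0) else all(d <= 0)
        if (!ok) msg <- c(msg, "thresholds violate the nesting invariant")
    }
    if (length(msg)) msg else TRUE
})

#' EvidenceIntervals: the up-to-nine strength intervals of a calibrated tool
#'
#' Partition of the score line into benign very strong ... benign supporting,
#' indeterminate, pathogenic supporting ... pathogenic very strong intervals.
#' Pathogenic intervals are closed on the left (`[tau, next)`), benign
#' intervals closed on the right (`(prev, tau]`); the indeterminate region is
#' the open interval between the benign- and pathogenic-supporting
#' thresholds.  Strengths that were not met are absent and their range is
#' absorbed by the weaker neighbour (ultimately the indeterminate region), so
#' the intervals always cover the whole line disjointly.
#'
#' @slot table data.frame with columns `strength`, `direction`, `lower`,
#'   `upper`, `lower_closed`, `upper_closed` (bounds on the normalized scale).
#' @slot pathogenic,benign the two [ThresholdSet-class] objects.
#' @slot flipped whether the underlying scores were negated.
#' @export
setClass("EvidenceIntervals",
    representation(table = "data.frame", pathogenic = "ThresholdSet",
                   benign = "ThresholdSet", flipped = "logical"))

#' ValidationReport: interval LRs and population fractions
#'
#' Per-interval assessment of calibrated thresholds on an independent labeled
#' set (interval-based likelihood ratios, Eq.-10 style true-positive over
#' false-positive rate) and on an unlabeled population set (fraction of
#' variants per interval; variants without scores count as indeterminate).
#'
#' @slot table data.frame with one row per interval.
#' @slot nPathogenic,nBenign labeled class sizes evaluated.
#' @slot nPopulation population set size (0 when no population set given).
#' @export
setClass("ValidationReport",
    representation(table = "data.frame", nPathogenic = "numeric",
                   nBenign = "numeric", nPopulation = "numeric"))

setValidity("ValidationReport", function(object) {
    msg <- character()
    tab <- object@table
    if (object@nPopulation > 0) {
        s <- sum(tab$population_fraction)
        if (abs(s - 1) > 1e-9)
            msg <- c(msg, "population fractions must sum to 1")
    }
    if (any(tab$n_pathogenic < 0) || any(tab$n_benign < 0))
        msg <- c(msg, "counts must be non-negative")
    if (sum(tab$n_pathogenic) != object@nPathogenic ||
        sum(tab$n_benign) != object@nBenign)
        msg <- c(msg, "per-interval counts must sum to the evaluated set sizes")
    if (length(msg)) msg else TRUE
})

#' DistanceCurve: nearest-neighbour removal curve for prior estimation
#'
#' @slot fraction fraction-removed grid in `[0, 1]`, strictly increasing.
#' @slot distance mean nearest-neighbour removal distance at each grid point.
#' @slot nReps number of repetitions averaged.
#' @slot seed integer seed used (NA when none supplied).
#' @export
setClass("DistanceCurve",
    representation(fraction = "numeric", distance = "numeric",
                   nReps = "numeric", seed = "numeric"))

setValidity("DistanceCurve", function(object) {
    msg <- character()
    if (length(object@fraction) != length(object@distance))
        msg <- c(msg, "'fraction' and 'distance' lengths differ")
    if (any(object@distance < 0))
        msg <- c(msg, "distances must be non-negative")
    if (is.unsorted(object@fraction, strictly = TRUE))
        msg <- c(msg, "'fraction' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' ScoreModel: synthetic score generator specification
#'
#' Describes the two class-conditional score distributions, the mixture weight
#' of pathogenic variants among unlabeled variants, sample sizes and the
#' missing-score rate.  Distribution specs are lists with a `family`
#' (`"gaussian"` or `"beta"`) and its parameters (`mean`/`sd` or
#' `shape1`/`shape2`), so the analytic local lr+ is available in closed form
#' for ground-truth checks.
#'
#' @slot pathogenic,benign distribution spec lists.
#' @slot alpha mixture weight of the pathogenic component among unlabeled
#'   variants, in `[0, 1]`.
#' @slot nPathogenic,nBenign,nUnlabeled sample sizes (>= 0).
#' @slot missingness fraction of scores set to `NA`, in `[0, 1)`.
#' @export
setClass("ScoreModel",
    representation(pathogenic = "list", benign = "list", alpha = "numeric",
                   nPathogenic = "numeric", nBenign = "numeric",
                   nUnlabeled = "numeric", missingness = "numeric"))

setValidity("ScoreModel", function(object) {
    msg <- character()
    for (slot in c("pathogenic", "benign")) {
        spec <- slot(object, slot)
        if (is.null(spec$family) || !spec$family %in% c("gaussian", "beta"))
            msg <- c(msg, sprintf("'%s' must have family gaussian or beta", slot))
    }
    if (object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "'alpha' must lie in [0, 1]")
    if (any(c(object@nPathogenic, object@nBenign, object@nUnlabeled) < 0))
        msg <- c(msg, "sample sizes must be >= 0")
    if (object@missingness < 0 || object@missingness >= 1)
        msg <- c(msg, "'missingness' must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})
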