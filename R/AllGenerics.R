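#' @rdname EvidenceConfig-class
#' @param x an object.
#' @export
setGeneric("priorProb", function(x) standardGeneric("priorProb"))

#' @rdname EvidenceConfig-class
#' @export
setGeneric("scalingConstant", function(x) standardGeneric("scalingConstant"))

#' @rdname EvidenceConfig-class
#' @param direction `"pathogenic"` or `"benign"`.
#' @export
setGeneric("lrCutoffs", function(x, direction = "pathogenic")
    standardGeneric("lrCutoffs"))

#' @rdname EvidenceConfig-class
#' @export
setGeneric("posteriorCutoffs", function(x, direction = "pathogenic")
    standardGeneric("posteriorCutoffs"))

#' @rdname ScoreSet-class
#' @export
setGeneric("toolName", function(x) standardGeneric("toolName"))

#' @rdname ScoreSet-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Normalize score orientation to higher-is-pathogenic
#'
#' Tools that assign *lower* scores to pathogenic variants are mapped onto the
#' common higher-is-pathogenic scale by negation, an order-reversing transform
#' whose inverse is recorded so thresholds can be reported on the native
#' scale (see [nativeScore()]).  Already-normalized sets are returned
#' unchanged.
#'
#' @param x a [ScoreSet].
#' @return a [ScoreSet] with orientation `"higher"`.
#' @export
setGeneric("normalizeOrientation", function(x)
    standardGeneric("normalizeOrientation"))

#' Map normalized scores back to a tool's native scale
#'
#' @param x a [ScoreSet] or [CalibrationCurve-class] carrying the orientation flag.
#' @param s numeric scores on the normalized scale.
#' @return numeric scores on the native scale.
#' @export
setGeneric("nativeScore", function(x, s) standardGeneric("nativeScore"))

#' @rdname ThresholdSet-class
#' @param x an object.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
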