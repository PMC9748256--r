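## ScoreSet construction, orientation normalization and score-table IO.

#' Create a ScoreSet
#'
#' @param variantKey character vector of unique variant identifiers.
#' @param score numeric scores, `NA` allowed for missing predictions.
#' @param toolName identifier of the prediction tool.
#' @param orientation `"higher"` (default) if higher scores indicate
#'   pathogenicity on the native scale, `"lower"` otherwise.
#' @return a [ScoreSet].
#' @examples
#' ScoreSet(c("v1", "v2"), c(0.9, 0.1), "toolA")
#' @export
ScoreSet <- function(variantKey, score, toolName = "tool",
                     orientation = c("higher", "lower")) {
    orientation <- match.arg(orientation)
    new("ScoreSet", toolName = as.character(toolName),
        variantKey = as.character(variantKey), score = as.numeric(score),
        orientation = orientation, flipped = FALSE)
}

#' @describeIn ScoreSet-class tool identifier.
#' @export
setMethod("toolName", "ScoreSet", function(x) x@toolName)

#' @describeIn ScoreSet-class named numeric vector of scores.
#' @export
setMethod("scores", "ScoreSet", function(x)
    setNames(x@score, x@variantKey))

#' @describeIn ScoreSet-class number of variants.
#' @param x a [ScoreSet].
#' @export
setMethod("length", "ScoreSet", function(x) length(x@score))

setMethod("show", "ScoreSet", function(object) {
    cat(sprintf("ScoreSet '%s': %d variants (%d with scores), orientation %s%s\n",
                object@toolName, length(object@score),
                sum(!is.na(object@score)), object@orientation,
                if (object@flipped) " (normalized by negation)" else ""))
})

#' @rdname normalizeOrientation
#' @export
setMethod("normalizeOrientation", "ScoreSet", function(x) {
    if (x@orientation == "higher") return(x)
    x@score <- -x@score
    x@orientation <- "higher"
    x@flipped <- TRUE
    validObject(x)
    x
})

#' @rdname nativeScore
#' @export
setMethod("nativeScore", "ScoreSet", function(x, s)
    if (x@flipped) -s else s)

#' @rdname nativeScore
#' @export
setMethod("nativeScore", "CalibrationCurve", function(x, s)
    if (x@flipped) -s else s)

#' Read a delimited score or label table
#'
#' `readScoreTable()` expects columns `variant_key` and `score` (extra columns
#' are ignored); `readLabelTable()` expects `variant_key` and `label` with
#' labels in P/LP/B/LB (mapped to pathogenic-like and benign-like).
#'
#' @param path path to a tab-delimited file with a header line.
#' @param toolName,orientation passed to [ScoreSet()].
#' @return `readScoreTable()`: a [ScoreSet]; `readLabelTable()`: a data.frame
#'   with columns `variant_key` and `label` (`"pathogenic"`/`"benign"`).
#' @export
readScoreTable <- function(path, toolName = "tool", orientation = "higher") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("variant_key", "score") %in% names(tab)))
        stop("score table needs columns 'variant_key' and 'score'")
    ScoreSet(tab$variant_key, tab$score, toolName, orientation)
}

#' @rdname readScoreTable
#' @export
readLabelTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("variant_key", "label") %in% names(tab)))
        stop("label table needs columns 'variant_key' and 'label'")
    data.frame(variant_key = tab$variant_key,
               label = normalizeLabels(tab$label),
               stringsAsFactors = FALSE)
}

#' Collapse clinical significance labels to the two calibration classes
#'
#' P/LP (any case, with or without the "likely" prefix spelled out) map to
#' `"pathogenic"`; B/LB map to `"benign"`; anything else is an error.
#'
#' @param label character vector of clinical labels.
#' @return character vector of `"pathogenic"`/`"benign"`.
#' @export
normalizeLabels <- function(label) {
    key <- toupper(trimws(as.character(label)))
    map <- c(P = "pathogenic", LP = "pathogenic",
             PATHOGENIC = "pathogenic", "LIKELY PATHOGENIC" = "pathogenic",
             B = "benign", LB = "benign",
             BENIGN = "benign", "LIKELY BENIGN" = "benign")
    out <- unname(map[key])
    if (anyNA(out))
        stop("unrecognized labels: ",
             paste(unique(label[is.na(out)]), collapse = ", "))
    out
}
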