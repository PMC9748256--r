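## Threshold selection from a bounded calibration curve and construction of
## the up-to-nine evidence intervals.

#' Select the score threshold meeting an lr+ cutoff
#'
#' Pathogenic direction: the smallest observed score `tau` such that the
#' one-sided lower bound of the local lr+ meets the cutoff at *every*
#' observed score greater than or equal to `tau` (a suffix condition; a dip
#' anywhere above a candidate blocks it).  Benign direction: the largest
#' observed score `tau` such that the upper bound stays at or below the
#' reciprocal cutoff at every observed score up to `tau`.  Candidate
#' thresholds are restricted to the curve's observed scores; between observed
#' scores the bound is not interpolated.
#'
#' Comparisons happen on the posterior scale, to which lr+ cutoffs are
#' converted with the curve's prior (the two scales are monotonically
#' equivalent at fixed prior, and the posterior scale is numerically safe
#' near 0 and 1).
#'
#' @param curve a [CalibrationCurve-class] with bootstrap bounds.
#' @param lrCutoff positive likelihood-ratio cutoff for the strength sought
#'   (always the pathogenic-direction value; the benign direction uses its
#'   reciprocal internally).
#' @param direction `"pathogenic"` or `"benign"`.
#' @return the threshold score (normalized scale), or `NA` when the cutoff is
#'   never met.
#' @export
selectThreshold <- function(curve, lrCutoff,
                            direction = c("pathogenic", "benign")) {
    direction <- match.arg(direction)
    if (!length(curve@score)) stop("empty calibration curve")
    if (lrCutoff <= 0) stop("'lrCutoff' must be positive")
    if (direction == "pathogenic") {
        cut <- posteriorFromLR(lrCutoff, curve@prior)
        b <- curve@boundPathogenic
        b[!is.finite(b)] <- -Inf
        suffixMin <- rev(cummin(rev(b)))
        idx <- which(suffixMin >= cut)
        if (!length(idx)) return(NA_real_)
        curve@score[idx[1L]]
    } else {
        cut <- posteriorFromLR(1 / lrCutoff, curve@prior)
        b <- curve@boundBenign
        b[!is.finite(b)] <- Inf
        prefixMax <- cummax(b)
        idx <- which(prefixMax <= cut)
        if (!length(idx)) return(NA_real_)
        curve@score[idx[length(idx)]]
    }
}

#' Build the pathogenic and benign threshold sets
#'
#' Applies [selectThreshold()] at every strength cutoff of the configuration
#' in both directions.  The suffix/prefix construction makes the nesting
#' invariant (`tau_su <= tau_mo <= tau_st <= tau_vs` on the pathogenic side,
#' mirrored on the benign side) hold automatically; it is still verified, and
#' in the ragged-bound corner case a stronger threshold is clipped to the
#' weaker one with a warning.  Thresholds are also reported on the tool's
#' native scale.
#'
#' @param curve a [CalibrationCurve-class].
#' @param config an [EvidenceConfig-class].
#' @return named list with elements `pathogenic` and `benign`, each a
#'   [ThresholdSet-class].
#' @export
buildThresholdSets <- function(curve, config = evidenceConfig()) {
    out <- lapply(.DIRECTIONS, function(dir) {
        cuts <- lrCutoffs(config, "pathogenic")
        th <- vapply(cuts, function(ct)
            selectThreshold(curve, ct, dir), numeric(1))
        ## enforce nesting: a stronger threshold never claims a laxer score
        met <- !is.na(th)
        if (any(met)) {
            run <- if (dir == "pathogenic") cummax(th[met]) else cummin(th[met])
            if (any(run != th[met])) {
                warning("clipping thresholds to restore nesting invariant")
                th[met] <- run
            }
            ## unmet weaker strength invalidates stronger ones
            firstUnmet <- which(!met)[1L]
            if (!is.na(firstUnmet) && any(met[seq_along(met) > firstUnmet])) {
                warning("dropping strengths met above an unmet weaker one")
                th[seq_along(th) > firstUnmet] <- NA_real_
            }
        }
        new("ThresholdSet", direction = dir, threshold = th,
            nativeThreshold = setNames(nativeScore(curve, th), names(th)),
            lrCutoff = if (dir == "pathogenic") cuts else 1 / cuts)
    })
    names(out) <- .DIRECTIONS
    out
}

#' @describeIn ThresholdSet-class named thresholds (normalized scale).
#' @export
setMethod("thresholds", "ThresholdSet", function(x) x@threshold)

setMethod("show", "ThresholdSet", function(object) {
    cat(sprintf("ThresholdSet (%s):\n", object@direction))
    disp <- ifelse(is.na(object@threshold), "-",
                   format(signif(object@threshold, 4)))
    for (i in seq_along(disp))
        cat(sprintf("  %-12s lr+ %-8s tau = %s\n",
                    names(object@threshold)[i],
                    format(signif(object@lrCutoff[i], 4)), disp[i]))
})

#' Construct the evidence intervals from two threshold sets
#'
#' @param thresholdSets list with `pathogenic` and `benign` [ThresholdSet-class]s,
#'   as returned by [buildThresholdSets()], or a [CalibrationCurve-class] (the
#'   threshold sets are then built with `config`).
#' @param config an [EvidenceConfig-class] (used only when a curve is given).
#' @return an [EvidenceIntervals-class].
#' @export
evidenceIntervals <- function(thresholdSets, config = evidenceConfig()) {
    if (is(thresholdSets, "CalibrationCurve"))
        thresholdSets <- buildThresholdSets(thresholdSets, config)
    pth <- thresholdSets$pathogenic
    ben <- thresholdSets$benign
    stopifnot(is(pth, "ThresholdSet"), is(ben, "ThresholdSet"))

    rows <- list()
    ## benign side, strongest met strength first: (prev, tau] intervals
    bth <- ben@threshold
    metB <- which(!is.na(bth))
    prev <- -Inf
    for (i in sort(metB, decreasing = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
            strength = names(bth)[i], direction = "benign",
            lower = prev, upper = bth[[i]],
            lower_closed = FALSE, upper_closed = TRUE)
        prev <- bth[[i]]
    }
    benEdge <- prev                            # tau^B_su or -Inf
    pthTh <- pth@threshold
    metP <- which(!is.na(pthTh))
    pathEdge <- if (length(metP)) pthTh[[metP[1L]]] else Inf
    rows[[length(rows) + 1L]] <- data.frame(
        strength = "indeterminate", direction = "none",
        lower = benEdge, upper = pathEdge,
        lower_closed = FALSE, upper_closed = FALSE)
    ## pathogenic side, weakest first: [tau, next) intervals
    if (length(metP)) {
        bounds <- c(pthTh[metP], Inf)
        for (k in seq_along(metP)) {
            i <- metP[k]
            rows[[length(rows) + 1L]] <- data.frame(
                strength = names(pthTh)[i], direction = "pathogenic",
                lower = bounds[[k]], upper = bounds[[k + 1L]],
                lower_closed = TRUE, upper_closed = FALSE)
        }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    allTh <- c(pth@threshold, ben@threshold)
    allNat <- c(pth@nativeThreshold, ben@nativeThreshold)
    keep <- !is.na(allTh) & allTh != 0
    new("EvidenceIntervals", table = tab, pathogenic = pth, benign = ben,
        flipped = any(keep) && all(allNat[keep] == -allTh[keep]))
}

setMethod("show", "EvidenceIntervals", function(object) {
    tab <- object@table
    fmt <- function(v) ifelse(is.finite(v), format(signif(v, 4)),
                              ifelse(v > 0, "Inf", "-Inf"))
    cat("EvidenceIntervals (normalized scale):\n")
    for (i in seq_len(nrow(tab)))
        cat(sprintf("  %s%s, %s%s  %s %s\n",
                    if (tab$lower_closed[i]) "[" else "(",
                    fmt(tab$lower[i]), fmt(tab$upper[i]),
                    if (tab$upper_closed[i]) "]" else ")",
                    tab$direction[i], tab$strength[i]))
})

#' The nine interval labels in score order
#'
#' @return character vector from `benign.very_strong` up to
#'   `pathogenic.very_strong`.
#' @export
strengthLevels <- function() {
    c(paste("benign", rev(.STRENGTHS), sep = "."), "indeterminate",
      paste("pathogenic", .STRENGTHS, sep = "."))
}

#' Assign evidence strengths to scores
#'
#' Maps each score to exactly one interval label.  Pathogenic intervals are
#' closed on the left (a score exactly at the supporting threshold earns
#' supporting evidence), benign intervals closed on the right; `NA` scores
#' (missing predictions) map to `"indeterminate"`.
#'
#' @param score numeric scores on the normalized scale (NA allowed).
#' @param intervals an [EvidenceIntervals-class].
#' @return character vector of labels from [strengthLevels()].
#' @export
assignStrength <- function(score, intervals) {
    stopifnot(is(intervals, "EvidenceIntervals"))
    out <- rep("indeterminate", length(score))
    bth <- intervals@benign@threshold
    for (st in .STRENGTHS) {                  # weakest to strongest
        t <- bth[[st]]
        if (!is.na(t)) out[!is.na(score) & score <= t] <-
            paste("benign", st, sep = ".")
    }
    pth <- intervals@pathogenic@threshold
    for (st in .STRENGTHS) {
        t <- pth[[st]]
        if (!is.na(t)) out[!is.na(score) & score >= t] <-
            paste("pathogenic", st, sep = ".")
    }
    out
}

#' Rebuild threshold sets from a table written by [thresholdTable()]
#'
#' @param tab data.frame with columns `direction`, `strength`, `lr_cutoff`,
#'   `threshold`, `native_threshold`.
#' @return named list with `pathogenic` and `benign` [ThresholdSet-class]s.
#' @export
thresholdsFromTable <- function(tab) {
    out <- lapply(.DIRECTIONS, function(dir) {
        sub <- tab[tab$direction == dir, ]
        sub <- sub[match(.STRENGTHS, sub$strength), ]
        new("ThresholdSet", direction = dir,
            threshold = setNames(as.numeric(sub$threshold), .STRENGTHS),
            nativeThreshold = setNames(as.numeric(sub$native_threshold),
                                       .STRENGTHS),
            lrCutoff = setNames(as.numeric(sub$lr_cutoff), .STRENGTHS))
    })
    names(out) <- .DIRECTIONS
    out
}

#' Thresholds as a Table-2-style data.frame
#'
#' One row per strength and direction with normalized and native-scale
#' thresholds; `NA` marks strengths the tool did not reach.
#'
#' @param thresholdSets list with `pathogenic` and `benign` [ThresholdSet-class]s.
#' @return data.frame.
#' @export
thresholdTable <- function(thresholdSets) {
    do.call(rbind, lapply(thresholdSets, function(ts) data.frame(
        direction = ts@direction, strength = names(ts@threshold),
        lr_cutoff = unname(ts@lrCutoff), threshold = unname(ts@threshold),
        native_threshold = unname(ts@nativeThreshold), row.names = NULL)))
}
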