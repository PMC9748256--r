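## Validation of calibrated intervals on independent data: interval-based
## likelihood ratios, population fractions, fixed-threshold assessment and
## multi-tool consensus curves.

.inInterval <- function(score, lower, upper, lowerClosed, upperClosed) {
    ok <- !is.na(score)
    lowOk <- if (lowerClosed) score >= lower else score > lower
    upOk <- if (upperClosed) score <= upper else score < upper
    ok & lowOk & upOk
}

#' Interval-based positive likelihood ratio
#'
#' The global likelihood ratio restricted to a score interval: the fraction
#' of pathogenic variants whose score falls inside the interval divided by
#' the fraction of benign variants inside it (true-positive rate over
#' false-positive rate).  Computed unweighted by default, matching its use on
#' an independent test set; `weight` multiplies the benign denominator for
#' the weighted variant used in mediant checks against the calibration
#' curve.  A zero benign denominator with a positive numerator gives `Inf`; a
#' 0/0 interval gives `NaN` (undefined).
#'
#' @param score numeric scores of the labeled evaluation set.
#' @param label class labels (coerced via [normalizeLabels()]).
#' @param lower,upper interval bounds.
#' @param lowerClosed,upperClosed boundary inclusion flags.
#' @param weight benign weight (default 1 = unweighted).
#' @return positive numeric, `Inf`, or `NaN`.
#' @export
intervalLR <- function(score, label, lower, upper, lowerClosed = TRUE,
                       upperClosed = FALSE, weight = 1) {
    label <- normalizeLabels(label)
    isPath <- label == "pathogenic"
    nP <- sum(isPath)
    nB <- sum(!isPath)
    if (nP == 0 || nB == 0)
        stop("labeled set must contain both classes")
    inside <- .inInterval(score, lower, upper, lowerClosed, upperClosed)
    tp <- sum(inside & isPath) / nP
    fp <- sum(inside & !isPath) / nB
    if (tp == 0 && fp == 0) return(NaN)
    if (fp == 0) return(Inf)
    tp / (weight * fp)
}

#' Validate evidence intervals on independent data
#'
#' For each calibrated interval, computes the unweighted interval likelihood
#' ratio on an independent labeled set along with per-class counts, the pass
#' verdict against the strength's cutoff (pathogenic intervals must reach at
#' least the cutoff, benign intervals must stay at or below the reciprocal
#' cutoff), and — when a population score set is supplied — the fraction of
#' population variants falling in the interval (missing scores count toward
#' indeterminate).
#'
#' @param intervals an [EvidenceIntervals-class].
#' @param score,label labeled evaluation scores and labels.
#' @param population optional numeric population scores (NA = missing).
#' @param config an [EvidenceConfig-class] supplying the cutoffs.
#' @return a [ValidationReport-class].
#' @export
validateThresholds <- function(intervals, score, label, population = NULL,
                               config = evidenceConfig()) {
    stopifnot(is(intervals, "EvidenceIntervals"))
    label <- normalizeLabels(label)
    isPath <- label == "pathogenic"
    nP <- sum(isPath)
    nB <- sum(!isPath)
    if (nP == 0 || nB == 0) stop("labeled set must contain both classes")
    tab <- intervals@table
    cutsP <- lrCutoffs(config, "pathogenic")

    assigned <- assignStrength(score, intervals)
    rowLabel <- ifelse(tab$direction == "none", "indeterminate",
                       paste(tab$direction, tab$strength, sep = "."))
    nPathIn <- vapply(rowLabel, function(l)
        sum(assigned == l & isPath), numeric(1))
    nBenIn <- vapply(rowLabel, function(l)
        sum(assigned == l & !isPath), numeric(1))
    ## NA scores are assigned indeterminate by assignStrength already
    tp <- nPathIn / nP
    fp <- nBenIn / nB
    lr <- ifelse(nPathIn == 0 & nBenIn == 0, NaN, tp / fp)

    pass <- rep(NA, nrow(tab))
    for (i in seq_len(nrow(tab))) {
        st <- tab$strength[i]
        if (tab$direction[i] == "pathogenic")
            pass[i] <- is.finite(lr[i]) && lr[i] >= cutsP[[st]] ||
                is.infinite(lr[i]) && lr[i] > 0
        else if (tab$direction[i] == "benign")
            pass[i] <- !is.nan(lr[i]) && lr[i] <= 1 / cutsP[[st]]
    }

    popFrac <- rep(NA_real_, nrow(tab))
    nPop <- 0
    if (!is.null(population)) {
        nPop <- length(population)
        popAssigned <- assignStrength(population, intervals)
        popFrac <- vapply(rowLabel, function(l)
            sum(popAssigned == l) / nPop, numeric(1))
    }

    out <- cbind(tab,
                 data.frame(n_pathogenic = unname(nPathIn),
                            n_benign = unname(nBenIn),
                            interval_lr = unname(lr), pass = unname(pass),
                            population_fraction = unname(popFrac)))
    new("ValidationReport", table = out, nPathogenic = nP, nBenign = nB,
        nPopulation = nPop)
}

#' Population fractions per evidence interval
#'
#' @param intervals an [EvidenceIntervals-class].
#' @param population numeric population scores (NA = missing prediction,
#'   counted as indeterminate).
#' @return named numeric vector over [strengthLevels()], summing to 1.
#' @export
populationFractions <- function(intervals, population) {
    if (!length(population)) stop("'population' must be non-empty")
    assigned <- assignStrength(population, intervals)
    lv <- strengthLevels()
    out <- vapply(lv, function(l) sum(assigned == l), numeric(1))
    out / length(population)
}

#' @rdname ValidationReport-class
#' @param x a [ValidationReport-class].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ValidationReport", function(x, ...) x@table)

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf(
        "ValidationReport: %g pathogenic, %g benign labeled variants%s\n",
        object@nPathogenic, object@nBenign,
        if (object@nPopulation > 0)
            sprintf(", %g population variants", object@nPopulation) else ""))
    tab <- object@table
    tab$interval_lr <- signif(tab$interval_lr, 4)
    if (all(is.na(tab$population_fraction)))
        tab$population_fraction <- NULL
    else tab$population_fraction <- signif(tab$population_fraction, 4)
    print(tab, row.names = FALSE)
})

#' Assess a fixed (developer-recommended) threshold
#'
#' Looks up the local lr+ point estimate and its two-sided bootstrap interval
#' at a fixed score threshold (evaluated at the nearest observed score of the
#' calibration curve), determines the evidence strength achieved on the basis
#' of the point estimate, and reports the fraction of a population set at or
#' beyond the threshold.
#'
#' @param curve a [CalibrationCurve-class] with bootstrap quantiles.
#' @param threshold score threshold on the normalized scale; must fall
#'   inside the curve's observed score range.
#' @param direction `"pathogenic"` or `"benign"`: which tail of the score
#'   axis the threshold gates.
#' @param config an [EvidenceConfig-class].
#' @param population optional numeric population scores.
#' @return list with `lr`, `ci` (length-2), `strength` (`"not_met"` when no
#'   cutoff is reached), and `population_fraction` (`NA` without population
#'   scores).
#' @export
assessFixedThreshold <- function(curve, threshold,
                                 direction = c("pathogenic", "benign"),
                                 config = evidenceConfig(),
                                 population = NULL) {
    direction <- match.arg(direction)
    s <- curve@score
    if (threshold < s[1L] || threshold > s[length(s)])
        stop("threshold lies outside the observed score range")
    i <- which.min(abs(s - threshold))
    prior <- curve@prior
    lr <- curve@lrPlus[i]
    ci <- c(lrFromPosterior(curve@ciLower[i], prior),
            lrFromPosterior(curve@ciUpper[i], prior))
    cuts <- lrCutoffs(config, "pathogenic")
    strength <- "not_met"
    for (st in .STRENGTHS) {
        ok <- if (direction == "pathogenic") lr >= cuts[[st]]
              else lr <= 1 / cuts[[st]]
        if (ok) strength <- st
    }
    popFrac <- NA_real_
    if (!is.null(population)) {
        beyond <- if (direction == "pathogenic") population >= threshold
                  else population <= threshold
        popFrac <- sum(beyond, na.rm = TRUE) / length(population)
    }
    list(lr = lr, ci = ci, strength = strength,
         population_fraction = popFrac)
}

#' Consensus local lr+ over two or three tools
#'
#' Estimates the local positive likelihood ratio of a score *vector* by
#' counting labeled variants inside an axis-aligned neighbourhood around the
#' query, expanded isotropically in rank space (per-tool ranks over the
#' combined labeled + unlabeled variants remove scale differences between
#' tools) until it contains at least `minLabeled` labeled variants and at
#' least `minUnlabeledFrac` of the unlabeled variants.  Only variants with
#' scores from every tool contribute.
#'
#' @param scoreSets list of 2 or 3 [ScoreSet]s (orientations normalized
#'   automatically).
#' @param labels data.frame with `variant_key` and `label`.
#' @param at numeric matrix (or vector for a single query) of query score
#'   vectors, one row per query, columns matching `scoreSets`.
#' @param unlabeled optional list of numeric unlabeled score vectors (same
#'   order as `scoreSets`), used for the rank transform and the unlabeled
#'   window constraint; the unlabeled variants must be shared across tools,
#'   so the vectors must have equal length.
#' @param config an [EvidenceConfig-class].
#' @param settings a [calibrationSettings()] list (`weight` honoured;
#'   `edgeScaling` is not applied in rank space).
#' @return numeric vector of local lr+ estimates, one per query row.
#' @export
consensusCurve <- function(scoreSets, labels, at, unlabeled = NULL,
                           config = evidenceConfig(),
                           settings = calibrationSettings()) {
    k <- length(scoreSets)
    if (!k %in% c(2L, 3L)) stop("need 2 or 3 score sets")
    sets <- lapply(scoreSets, function(s) scores(normalizeOrientation(
        if (is(s, "ScoreSet")) s else .resolveScores(s))))
    lab <- data.frame(variant_key = labels$variant_key,
                      label = normalizeLabels(labels$label))
    keys <- lab$variant_key
    mat <- sapply(sets, function(sc) unname(sc[keys]))
    complete <- stats::complete.cases(mat)
    if (sum(complete) < settings$minLabeled)
        stop("insufficient variants with complete scores across tools")
    mat <- mat[complete, , drop = FALSE]
    isPath <- lab$label[complete] == "pathogenic"

    if (!is.null(unlabeled)) {
        stopifnot(length(unlabeled) == k)
        umat <- do.call(cbind, lapply(unlabeled, as.numeric))
        umat <- umat[stats::complete.cases(umat), , drop = FALSE]
    } else umat <- matrix(numeric(), ncol = k)

    if (is.null(dim(at))) at <- matrix(at, ncol = k, byrow = TRUE)
    ## per-tool rank transform via the empirical cdf of observed scores
    ref <- lapply(seq_len(k), function(j) sort(c(mat[, j], umat[, j])))
    toRank <- function(v, j) {
        findInterval(v, ref[[j]]) / length(ref[[j]])
    }
    rmat <- sapply(seq_len(k), function(j) toRank(mat[, j], j))
    rumat <- if (nrow(umat)) sapply(seq_len(k), function(j)
        toRank(umat[, j], j)) else umat
    rat <- sapply(seq_len(k), function(j) toRank(at[, j], j))
    if (is.null(dim(rat))) rat <- matrix(rat, ncol = k)

    w <- settings$weight %||%
        benignWeight(sum(isPath), sum(!isPath), priorProb(config))
    minUnl <- settings$minUnlabeledFrac * nrow(umat)

    apply(rat, 1L, function(q) {
        dLab <- apply(abs(sweep(rmat, 2L, q)), 1L, max)   # Chebyshev radius
        dUnl <- if (nrow(umat))
            apply(abs(sweep(rumat, 2L, q)), 1L, max) else numeric()
        cand <- sort(unique(c(0, dLab, dUnl)))
        r <- NA_real_
        for (e in cand) {
            if (sum(dLab <= e) + 1e-9 >= settings$minLabeled &&
                (minUnl <= 0 || sum(dUnl <= e) + 1e-9 >= minUnl)) {
                r <- e
                break
            }
        }
        if (is.na(r)) stop("window requirements unsatisfiable in rank space")
        inW <- dLab <= r
        p <- sum(inW & isPath)
        b <- sum(inW & !isPath)
        post <- p / (p + w * b)
        lrFromPosterior(post, priorProb(config))
    })
}
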