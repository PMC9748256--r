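## Positive-unlabeled estimation of the prior probability of pathogenicity
## from one-dimensional scores, via nearest-neighbour removal distance
## curves.

#' Nearest-neighbour removal distance curve
#'
#' One pass of the positive-unlabeled prior estimator: sample (with
#' replacement) as many labeled-positive scores as the sampling budget
#' allows — the positive-set size capped at the unlabeled-set size — then,
#' for each sampled positive in turn, remove the closest remaining unlabeled
#' score and record its absolute distance.  While the unlabeled set still
#' contains scores resembling the positive distribution the distances stay
#' small; once that sub-population is exhausted they jump, and the jump
#' location along the fraction-removed axis estimates the fraction of
#' positive-like scores among the unlabeled.
#'
#' @param positives numeric vector of labeled-positive scores.
#' @param unlabeled numeric vector of unlabeled reference scores, at least
#'   as large as the positive resample.
#' @param seed optional integer seed.
#' @return a [DistanceCurve-class].
#' @export
distanceCurve <- function(positives, unlabeled, seed = NULL) {
    positives <- positives[!is.na(positives)]
    unlabeled <- unlabeled[!is.na(unlabeled)]
    if (!length(positives) || !length(unlabeled))
        stop("'positives' and 'unlabeled' must be non-empty")
    n <- min(length(positives), length(unlabeled))
    if (!is.null(seed)) set.seed(seed)
    qs <- positives[sample.int(length(positives), n, replace = TRUE)]
    d <- cpp_distcurve(qs, unlabeled)
    new("DistanceCurve", fraction = seq_len(n) / n, distance = d,
        nReps = 1, seed = if (is.null(seed)) NA_real_ else seed)
}

setMethod("show", "DistanceCurve", function(object) {
    cat(sprintf(
        "DistanceCurve: %d removals, %g repetition(s), max distance %.4g\n",
        length(object@fraction), object@nReps, max(object@distance)))
})

## Knee detector: the removal curve (with the origin prepended) is smoothed
## with a centred moving average whose width is 5% of the grid, and the
## fraction with the steepest smoothed ascent is returned.  A centred moving
## average turns a step at fraction a into a linear ramp centred on a, so
## the maximal slope sits at the step location itself; the discrete second
## difference, by contrast, peaks at the ramp corners, half a smoothing
## window away from the step.
.detectInflection <- function(fraction, distance,
                              method = c("slope", "curvature")) {
    method <- match.arg(method)
    x <- c(0, fraction)
    y <- c(0, distance)
    if (diff(range(y)) <= 0) return(NA_real_)   # flat curve: not estimable
    win <- max(3L, as.integer(round(0.05 * length(y))))
    if (win %% 2L == 0L) win <- win + 1L
    half <- win %/% 2L
    cs <- cumsum(c(0, y))
    n <- length(y)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    if (method == "slope") {
        slope <- diff(sm) / diff(x)
        i <- which.max(slope)
        ## midpoint of the steepest segment
        (x[i] + x[i + 1L]) / 2
    } else {
        d2 <- diff(sm, differences = 2L)
        x[which.max(d2) + 1L]
    }
}

#' Estimate the prior probability of pathogenicity
#'
#' Averages `nReps` nearest-neighbour removal curves ([distanceCurve()]) and
#' returns the fraction removed at the curve's knee, detected as the point
#' of steepest ascent of the smoothed averaged curve (see the methods
#' vignette for the detector choice; `detector = "curvature"` selects the
#' maximal discrete second difference instead).  The estimate is scale
#' invariant and always lies in `[0, 1]`; a perfectly flat curve returns
#' `NA` (not estimable).
#'
#' @param positives,unlabeled numeric score vectors.
#' @param nReps number of repetitions to average (default 10).
#' @param seed optional integer seed (each repetition advances the RNG).
#' @param detector `"slope"` (default) or `"curvature"`.
#' @return list with `estimate`, `curve` (a [DistanceCurve-class] of the averaged
#'   distances) and `per_rep` (per-repetition estimates).
#' @examples
#' set.seed(7)
#' pos <- rnorm(2000, 4)
#' unl <- c(rnorm(600, 4), rnorm(1400, 0))   # 30% positive-like
#' estimatePrior(pos, unl, nReps = 3, seed = 7)$estimate
#' @export
estimatePrior <- function(positives, unlabeled, nReps = 10, seed = NULL,
                          detector = c("slope", "curvature")) {
    detector <- match.arg(detector)
    if (nReps < 1) stop("'nReps' must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    curves <- vector("list", nReps)
    for (r in seq_len(nReps))
        curves[[r]] <- distanceCurve(positives, unlabeled, seed = NULL)
    dist <- rowMeans(do.call(cbind, lapply(curves, slot, "distance")))
    frac <- curves[[1L]]@fraction
    perRep <- vapply(curves, function(cv)
        .detectInflection(cv@fraction, cv@distance, detector), numeric(1))
    avg <- new("DistanceCurve", fraction = frac, distance = dist,
               nReps = nReps, seed = if (is.null(seed)) NA_real_ else seed)
    list(estimate = .detectInflection(frac, dist, detector),
         curve = avg, per_rep = perRep)
}
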