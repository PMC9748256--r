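## Local posterior / local lr+ curve estimation: adaptive sliding windows,
## prior-matching benign weighting, stratified bootstrap bounds.

#' Calibration settings
#'
#' Bundles the tunable parameters of the local calibration procedure.
#'
#' @param minLabeled minimum number of labeled (pathogenic + benign combined)
#'   variants each window must contain (default 100).
#' @param minUnlabeledFrac minimum fraction of the unlabeled reference set
#'   each window must contain (default 0.03).
#' @param nBootstrap bootstrap replicates for the confidence bounds (default
#'   10000).  Memory for the bootstrap grows as `nBootstrap` times the number
#'   of unique scores.
#' @param alpha one-sided level of the conservative bounds (default 0.05,
#'   i.e. one-sided 95% bounds).
#' @param edgeScaling `"proportional"` (default) scales the window
#'   requirements by the fraction of the window lying inside the observed
#'   score range when a window is truncated at the range ends; `"none"`
#'   applies the full requirements everywhere.
#' @param weight benign weight `w`; `NULL` (default) derives it from the
#'   class counts and the prior via [benignWeight()].
#' @return a validated list of settings.
#' @export
calibrationSettings <- function(minLabeled = 100, minUnlabeledFrac = 0.03,
                                nBootstrap = 10000, alpha = 0.05,
                                edgeScaling = c("proportional", "none"),
                                weight = NULL) {
    edgeScaling <- match.arg(edgeScaling)
    stopifnot(minLabeled >= 1, minUnlabeledFrac >= 0, minUnlabeledFrac <= 1,
              nBootstrap >= 0, alpha > 0, alpha < 0.5,
              is.null(weight) || weight > 0)
    list(minLabeled = minLabeled, minUnlabeledFrac = minUnlabeledFrac,
         nBootstrap = nBootstrap, alpha = alpha, edgeScaling = edgeScaling,
         weight = weight)
}

#' Benign weight matching the calibration set to the prior
#'
#' The labeled calibration set is typically heavily enriched for pathogenic
#' variants relative to the population.  Weighting every benign variant by
#' `w = (nPathogenic / nBenign) / priorOdds(prior)` makes a window whose
#' class composition equals the full data set's produce a posterior equal to
#' the configured prior.  The weight is recomputed per tool because scores
#' are not available for every variant.
#'
#' @param nPathogenic,nBenign labeled class sizes (variants with scores).
#' @param prior prior probability of pathogenicity.
#' @return positive numeric weight.
#' @examples
#' benignWeight(4000, 7834, 0.0441)   # about 11.07
#' @export
benignWeight <- function(nPathogenic, nBenign, prior) {
    if (nPathogenic <= 0) stop("'nPathogenic' must be positive")
    if (nBenign <= 0) stop("'nBenign' must be positive")
    (nPathogenic / nBenign) / priorOdds(prior)
}

#' Adaptive window half-width at a score
#'
#' The smallest half-width `eps` (restricted to observed distances
#' `|x - s|`) such that the closed window `[s - eps, s + eps]` contains at
#' least `minLabeled` labeled scores and at least `minUnlabeledFrac` of the
#' unlabeled scores.  Under proportional edge scaling, windows truncated by
#' the observed score range have both requirements multiplied by the fraction
#' of the window lying inside the range.
#'
#' This reference implementation evaluates the definition directly; the curve
#' estimator ([calibrateScores()]) computes the same quantity in compiled
#' code.
#'
#' @param s numeric vector of evaluation scores.
#' @param labeledScores,unlabeledScores numeric score vectors (no NAs).
#' @param settings a [calibrationSettings()] list.
#' @param range observed score range used for edge scaling; defaults to the
#'   range of all supplied scores.
#' @return numeric vector of half-widths.
#' @export
windowHalfwidth <- function(s, labeledScores, unlabeledScores = numeric(),
                            settings = calibrationSettings(),
                            range = NULL) {
    if (!length(labeledScores)) stop("'labeledScores' must be non-empty")
    minLab <- settings$minLabeled
    minUnl <- settings$minUnlabeledFrac * length(unlabeledScores)
    if (is.null(range))
        range <- base::range(c(labeledScores, unlabeledScores))
    vapply(s, .halfwidthOne, numeric(1),
           lab = labeledScores, unl = unlabeledScores,
           minLab = minLab, minUnl = minUnl,
           edgeScale = settings$edgeScaling == "proportional",
           lo = range[1L], hi = range[2L])
}

## definition-level scan over candidate half-widths for a single score
.halfwidthOne <- function(s, lab, unl, minLab, minUnl, edgeScale, lo, hi) {
    dLab <- abs(lab - s)
    dUnl <- abs(unl - s)
    cand <- sort(unique(c(0, dLab, dUnl)))
    for (e in cand) {
        f <- if (edgeScale && e > 0)
            (min(s + e, hi) - max(s - e, lo)) / (2 * e) else 1
        if (sum(dLab <= e) + 1e-9 >= minLab * f &&
            (minUnl <= 0 || sum(dUnl <= e) + 1e-9 >= minUnl * f))
            return(e)
    }
    stop(sprintf(paste0("window requirements unsatisfiable at score %g even ",
                        "at full range (labeled >= %g, unlabeled >= %g)"),
                 s, minLab, minUnl))
}

.resolveScores <- function(x) {
    if (is(x, "ScoreSet")) return(normalizeOrientation(x))
    if (is.data.frame(x)) {
        if (!all(c("variant_key", "score") %in% names(x)))
            stop("score data.frame needs columns 'variant_key' and 'score'")
        return(ScoreSet(x$variant_key, x$score))
    }
    stop("'scores' must be a ScoreSet or a data.frame")
}

.resolveUnlabeled <- function(x) {
    if (is.null(x)) return(numeric())
    if (is(x, "ScoreSet")) return(scores(normalizeOrientation(x)))
    if (is.data.frame(x)) return(x$score)
    as.numeric(x)
}

#' Estimate the local posterior / local lr+ curve for one tool
#'
#' For every unique score of the labeled calibration variants, counts
#' pathogenic and benign variants inside an adaptive window (see
#' [windowHalfwidth()]), forms the weighted local posterior
#' `P / (P + w * B)`, converts it to a local positive likelihood ratio, and
#' (unless `nBootstrap` is 0) attaches one-sided bootstrap confidence bounds
#' obtained by resampling labeled variants with replacement within each class
#' while keeping the unlabeled set and the weight fixed.  Bounds are clamped
#' to the conservative side of the point estimate.  Windows containing no
#' (weighted) benign variants yield posterior 1 and an infinite lr+.
#'
#' Variants with missing scores are excluded here; downstream they count
#' toward the indeterminate interval.
#'
#' @param scores a [ScoreSet] (orientation is normalized automatically) or a
#'   data.frame with columns `variant_key` and `score`.
#' @param labels data.frame with columns `variant_key` and `label`
#'   (P/LP/B/LB or `"pathogenic"`/`"benign"`).
#' @param unlabeled unlabeled reference scores: numeric vector, [ScoreSet]
#'   or data.frame with a `score` column.
#' @param config an [EvidenceConfig-class]; its prior enters the posterior/lr+
#'   conversion and the default benign weight.
#' @param settings a [calibrationSettings()] list.
#' @param seed optional integer seed for the bootstrap.
#' @return a [CalibrationCurve-class].
#' @examples
#' sim <- simulateScores(scoreModel(nPathogenic = 500, nBenign = 500,
#'                                  nUnlabeled = 2000), seed = 1)
#' curve <- calibrateScores(sim$labeled[, c("variant_key", "score")],
#'                          sim$labeled[, c("variant_key", "label")],
#'                          sim$unlabeled$score,
#'                          settings = calibrationSettings(nBootstrap = 50),
#'                          seed = 1)
#' curve
#' @export
calibrateScores <- function(scores, labels, unlabeled = numeric(),
                            config = evidenceConfig(),
                            settings = calibrationSettings(), seed = NULL) {
    ss <- .resolveScores(scores)
    if (!all(c("variant_key", "label") %in% names(labels)))
        stop("'labels' needs columns 'variant_key' and 'label'")
    lab <- data.frame(variant_key = labels$variant_key,
                      label = normalizeLabels(labels$label))
    sc <- scores(ss)
    keep <- names(sc)[!is.na(sc)]
    lab <- lab[lab$variant_key %in% keep, ]
    if (!nrow(lab)) stop("no labeled variants with scores")
    x <- unname(sc[lab$variant_key])
    isPath <- lab$label == "pathogenic"
    pathScores <- x[isPath]
    benScores <- x[!isPath]
    if (!length(pathScores) || !length(benScores))
        stop("need labeled variants with scores in both classes")
    if (length(lab$variant_key) < settings$minLabeled)
        stop("fewer labeled variants with scores than 'minLabeled'")

    unl <- .resolveUnlabeled(unlabeled)
    unl <- sort(unl[!is.na(unl)])
    if (settings$minUnlabeledFrac > 0 && !length(unl))
        stop("'minUnlabeledFrac' > 0 requires unlabeled scores")

    w <- settings$weight %||%
        benignWeight(length(pathScores), length(benScores), priorProb(config))

    grid <- sort(unique(x))
    idxP <- match(pathScores, grid)
    idxB <- match(benScores, grid)
    pathCnt <- tabulate(idxP, length(grid))
    benCnt <- tabulate(idxB, length(grid))
    rng <- range(c(grid, unl))
    lo <- rng[1L]
    hi <- rng[2L]
    minUnl <- settings$minUnlabeledFrac * length(unl)
    edge <- settings$edgeScaling == "proportional"

    epsUnl <- cpp_unlab_eps(grid, unl, minUnl)
    pt <- cpp_local_curve(grid, as.numeric(pathCnt), as.numeric(benCnt), unl,
                          epsUnl, settings$minLabeled, minUnl, w, edge,
                          lo, hi)
    posterior <- pt$posterior
    lrPlus <- lrFromPosterior(posterior, priorProb(config))

    nBoot <- settings$nBootstrap
    if (nBoot >= 1) {
        if (!is.null(seed)) set.seed(seed)
        nP <- length(pathScores); nB <- length(benScores)
        mat <- matrix(NA_real_, nrow = nBoot, ncol = length(grid))
        for (b in seq_len(nBoot)) {
            cp <- tabulate(idxP[sample.int(nP, nP, replace = TRUE)],
                           length(grid))
            cb <- tabulate(idxB[sample.int(nB, nB, replace = TRUE)],
                           length(grid))
            mat[b, ] <- cpp_local_curve(grid, as.numeric(cp), as.numeric(cb),
                                        unl, epsUnl, settings$minLabeled,
                                        minUnl, w, edge, lo, hi)$posterior
        }
        a <- settings$alpha
        qs <- cpp_col_quantiles(mat, c(a, 1 - a, a / 2, 1 - a / 2))
        boundPath <- pmin(qs[1L, ], posterior)
        boundBen <- pmax(qs[2L, ], posterior)
        ciLower <- qs[3L, ]
        ciUpper <- qs[4L, ]
    } else {
        boundPath <- posterior
        boundBen <- posterior
        ciLower <- posterior
        ciUpper <- posterior
    }

    new("CalibrationCurve", score = grid, epsilon = pt$epsilon,
        nPathogenic = pt$n_pathogenic, nBenign = pt$n_benign,
        posterior = posterior, lrPlus = lrPlus,
        boundPathogenic = boundPath, boundBenign = boundBen,
        ciLower = ciLower, ciUpper = ciUpper,
        prior = priorProb(config), weight = w, nBoot = nBoot,
        settings = settings, toolName = toolName(ss), flipped = ss@flipped)
}

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve '%s': %d unique scores in [%.4g, %.4g]\n",
        object@toolName, length(object@score),
        min(object@score), max(object@score)))
    cat(sprintf("  prior %.4g, benign weight %.4g, %g bootstrap replicates\n",
                object@prior, object@weight, object@nBoot))
})

#' Curve as a data.frame
#'
#' @param x a [CalibrationCurve-class].
#' @param ... unused.
#' @return data.frame with one row per unique score.
#' @export
setMethod("as.data.frame", "CalibrationCurve", function(x, ...) {
    data.frame(score = x@score, epsilon = x@epsilon,
               n_pathogenic = x@nPathogenic, n_benign = x@nBenign,
               posterior = x@posterior, lr_plus = x@lrPlus,
               bound_pathogenic = x@boundPathogenic,
               bound_benign = x@boundBenign,
               ci_lower = x@ciLower, ci_upper = x@ciUpper)
})

#' Write / read a calibration curve as TSV
#'
#' The TSV carries the per-score columns of [as.data.frame()]; the companion
#' JSON manifest (written alongside when `manifest = TRUE`) records prior,
#' weight, settings and counts so a curve can be reloaded losslessly.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path output TSV path.
#' @param manifest write `<path>.json` with the curve metadata.
#' @export
writeCurve <- function(curve, path, manifest = TRUE) {
    write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (manifest) {
        meta <- list(tool = curve@toolName, prior = curve@prior,
                     weight = curve@weight, n_bootstrap = curve@nBoot,
                     flipped = curve@flipped, settings = curve@settings)
        jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                             digits = NA, null = "null")
    }
    invisible(path)
}

#' @rdname writeCurve
#' @param path TSV path written by [writeCurve()].
#' @return a [CalibrationCurve-class].
#' @export
readCurve <- function(path) {
    tab <- read.delim(path)
    metaPath <- paste0(path, ".json")
    meta <- if (file.exists(metaPath))
        jsonlite::read_json(metaPath, simplifyVector = TRUE)
    else list(tool = "tool", prior = 0.0441, weight = 1, n_bootstrap = 0,
              flipped = FALSE, settings = NULL)
    settings <- if (!is.null(meta$settings))
        do.call(calibrationSettings, meta$settings[setdiff(
            names(meta$settings), "weight")])
    else calibrationSettings(nBootstrap = 0)
    new("CalibrationCurve", score = tab$score, epsilon = tab$epsilon,
        nPathogenic = tab$n_pathogenic, nBenign = tab$n_benign,
        posterior = tab$posterior, lrPlus = tab$lr_plus,
        boundPathogenic = tab$bound_pathogenic,
        boundBenign = tab$bound_benign,
        ciLower = tab$ci_lower, ciUpper = tab$ci_upper,
        prior = meta$prior, weight = meta$weight, nBoot = meta$n_bootstrap,
        settings = settings, toolName = meta$tool,
        flipped = isTRUE(meta$flipped))
}
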