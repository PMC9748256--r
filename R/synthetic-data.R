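## Synthetic score and record generators with analytic ground truth, used
## throughout the test suite and the reproduction script.

#' Create a synthetic score model
#'
#' Defines class-conditional score distributions for pathogenic and benign
#' variants plus an unlabeled reference population drawn from their
#' `alpha` : `1 - alpha` mixture.  The defaults mirror the structure of a
#' clinical-archive calibration set paired with a population reference: a
#' labeled set of 4,000 pathogenic and 7,834 benign variants, a 40,000-variant
#' unlabeled set containing 4.41% pathogenic-like variants, bounded
#' Beta-distributed scores (like posterior-style tool outputs) and a 5%
#' missing-score rate.  Gaussian families are available for closed-form
#' checks (equal-variance Gaussians give `log lr+` linear in the score).
#'
#' @param pathogenic,benign distribution specs:
#'   `list(family = "beta", shape1 =, shape2 =)` or
#'   `list(family = "gaussian", mean =, sd =)`.
#' @param alpha fraction of pathogenic-like variants among unlabeled.
#' @param nPathogenic,nBenign,nUnlabeled sample sizes.
#' @param missingness fraction of scores replaced by `NA`.
#' @return a [ScoreModel-class].
#' @export
scoreModel <- function(pathogenic = list(family = "beta", shape1 = 6,
                                         shape2 = 2),
                       benign = list(family = "beta", shape1 = 2,
                                     shape2 = 6),
                       alpha = 0.0441, nPathogenic = 4000, nBenign = 7834,
                       nUnlabeled = 40000, missingness = 0.05) {
    new("ScoreModel", pathogenic = pathogenic, benign = benign,
        alpha = alpha, nPathogenic = nPathogenic, nBenign = nBenign,
        nUnlabeled = nUnlabeled, missingness = missingness)
}

#' Gaussian score model helper
#'
#' @param meanPath,meanBenign,sd Gaussian parameters (shared sd).
#' @param ... forwarded to [scoreModel()].
#' @return a [ScoreModel-class] with equal-variance Gaussian classes.
#' @export
gaussianScoreModel <- function(meanPath = 2, meanBenign = 0, sd = 1, ...) {
    scoreModel(pathogenic = list(family = "gaussian", mean = meanPath,
                                 sd = sd),
               benign = list(family = "gaussian", mean = meanBenign,
                             sd = sd), ...)
}

.rdist <- function(spec, n) {
    if (n == 0) return(numeric())
    switch(spec$family,
           gaussian = rnorm(n, spec$mean, spec$sd),
           beta = rbeta(n, spec$shape1, spec$shape2),
           stop("unknown family"))
}

.ddist <- function(spec, x) {
    switch(spec$family,
           gaussian = dnorm(x, spec$mean, spec$sd),
           beta = dbeta(x, spec$shape1, spec$shape2),
           stop("unknown family"))
}

#' Analytic local lr+ of a score model
#'
#' @param model a [ScoreModel-class].
#' @return function mapping scores to the density ratio
#'   `p(s | pathogenic) / p(s | benign)`.
#' @export
analyticLR <- function(model) {
    force(model)
    function(s) .ddist(model@pathogenic, s) / .ddist(model@benign, s)
}

#' Analytic score threshold where the local lr+ equals a cutoff
#'
#' Inverts the model's analytic density ratio at `lrCutoff` by root finding
#' on the log scale.  Requires a monotone likelihood ratio (checked on a
#' grid); for equal-variance Gaussians `N(mu_p, sd)` vs `N(mu_b, sd)` this
#' is the closed-form `s = (log cutoff * sd^2 + (mu_p^2 - mu_b^2) / 2) /
#' (mu_p - mu_b)`.
#'
#' @param model a [ScoreModel-class].
#' @param lrCutoff positive likelihood-ratio cutoff.
#' @return the score at which the analytic lr+ crosses `lrCutoff`.
#' @examples
#' analyticThreshold(gaussianScoreModel(), 2.406)   # (log 2.406 + 2) / 2
#' @export
analyticThreshold <- function(model, lrCutoff) {
    stopifnot(lrCutoff > 0)
    lrFun <- analyticLR(model)
    supp <- if (model@pathogenic$family == "beta" &&
                model@benign$family == "beta") c(1e-6, 1 - 1e-6)
            else {
                m <- c(model@pathogenic$mean %||% 0.5,
                       model@benign$mean %||% 0.5)
                sd <- max(model@pathogenic$sd %||% 1,
                          model@benign$sd %||% 1)
                c(min(m) - 8 * sd, max(m) + 8 * sd)
            }
    grid <- seq(supp[1L], supp[2L], length.out = 512L)
    lg <- log(lrFun(grid))
    finite <- is.finite(lg)
    if (any(diff(lg[finite]) < -1e-9))
        stop("model does not have a monotone likelihood ratio")
    f <- function(s) log(lrFun(s)) - log(lrCutoff)
    lo <- f(supp[1L]); hi <- f(supp[2L])
    if (is.nan(lo) || is.nan(hi) || lo > 0 || hi < 0)
        stop("cutoff outside the attainable lr+ range of the model")
    uniroot(f, supp, tol = 1e-10)$root
}

#' Simulate labeled and unlabeled score sets with ground truth
#'
#' @param model a [ScoreModel-class].
#' @param seed optional integer seed; identical seeds give identical output.
#' @return list with `labeled` (data.frame `variant_key`, `score`, `label`),
#'   `unlabeled` (data.frame `variant_key`, `score`, `is_pathogenic`), and
#'   `truth` (list: `lr` analytic density-ratio function, `alpha`,
#'   `threshold(lrCutoff)` analytic threshold function, `model`).
#' @export
simulateScores <- function(model, seed = NULL) {
    stopifnot(is(model, "ScoreModel"))
    if (!is.null(seed)) set.seed(seed)
    nP <- model@nPathogenic; nB <- model@nBenign; nU <- model@nUnlabeled
    pathScores <- .rdist(model@pathogenic, nP)
    benScores <- .rdist(model@benign, nB)
    nUP <- if (nU > 0) stats::rbinom(1L, nU, model@alpha) else 0L
    unlScores <- c(.rdist(model@pathogenic, nUP), .rdist(model@benign,
                                                         nU - nUP))
    unlPath <- rep(c(TRUE, FALSE), c(nUP, nU - nUP))
    if (nU > 0) {
        ord <- sample.int(nU)
        unlScores <- unlScores[ord]
        unlPath <- unlPath[ord]
    }
    maskNA <- function(x) {
        if (model@missingness > 0 && length(x))
            x[runif(length(x)) < model@missingness] <- NA_real_
        x
    }
    labeled <- data.frame(
        variant_key = sprintf("lab%06d", seq_len(nP + nB)),
        score = maskNA(c(pathScores, benScores)),
        label = rep(c("pathogenic", "benign"), c(nP, nB)),
        stringsAsFactors = FALSE)
    unlabeled <- data.frame(
        variant_key = sprintf("pop%06d", seq_len(nU)),
        score = maskNA(unlScores), is_pathogenic = unlPath,
        stringsAsFactors = FALSE)
    list(labeled = labeled, unlabeled = unlabeled,
         truth = list(lr = analyticLR(model), alpha = model@alpha,
                      threshold = function(lrCutoff)
                          analyticThreshold(model, lrCutoff),
                      model = model))
}

setMethod("show", "ScoreModel", function(object) {
    fmt <- function(spec) paste0(spec$family, "(",
        paste(unlist(spec[-1L]), collapse = ", "), ")")
    cat(sprintf(
        "ScoreModel: pathogenic %s vs benign %s\n  n = %g/%g labeled, %g unlabeled (alpha = %g), missingness %g\n",
        fmt(object@pathogenic), fmt(object@benign), object@nPathogenic,
        object@nBenign, object@nUnlabeled, object@alpha,
        object@missingness))
})

#' Synthetic variant-record fixture with known per-rule violations
#'
#' Builds a table of variant records in which every non-clean record
#' violates exactly one named filtering rule, so the expected survivor set
#' of the filter engine is the clean records by construction.
#'
#' Supported rules for `mode = "labeled"`: `af_high`, `not_missense`,
#' `gene_no_pathogenic`, `vus`, `zero_star`, `conflicting`, `training`;
#' for `mode = "population"`: `af_high`, `not_missense`,
#' `gene_no_pathogenic`, `fail_filter`, `low_gq`, `low_depth_rare`
#' (allele count below the break with insufficient depth), `region`,
#' `training`, `labeled_overlap`.  Plus `clean` in both modes.
#'
#' @param spec named integer vector/list of record counts per rule.
#' @param mode `"labeled"` or `"population"`.
#' @param seed optional integer seed (controls score jitter only).
#' @return list with `records`, `expected` (the clean subset), `config`
#'   (a matching [filterConfig()]), and for population mode `regions`
#'   (the BED-convention exclusion data.frame).
#' @export
makeRecordFixture <- function(spec, mode = c("labeled", "population"),
                              seed = NULL) {
    mode <- match.arg(mode)
    if (!is.null(seed)) set.seed(seed)
    spec <- unlist(spec)
    if (any(spec < 0)) stop("rule counts must be non-negative")
    allowed <- if (mode == "labeled")
        c("af_high", "not_missense", "gene_no_pathogenic", "vus",
          "zero_star", "conflicting", "training", "clean")
    else
        c("af_high", "not_missense", "gene_no_pathogenic", "fail_filter",
          "low_gq", "low_depth_rare", "region", "training",
          "labeled_overlap", "clean")
    if (!all(names(spec) %in% allowed))
        stop("unknown rule(s): ",
             paste(setdiff(names(spec), allowed), collapse = ", "))

    rules <- rep(names(spec), spec)
    n <- max(length(rules), 1L)
    base <- data.frame(
        chrom = "chr1",
        pos = 1000L + 10L * seq_len(n),
        ref = "A", alt = "G",
        gene = "GENE_OK",
        clinical_label = rep(c("P", "B"), length.out = n),
        review_stars = 2L,
        consequence = "missense",
        af_exomes = round(runif(n, 0, 0.005), 6),
        af_genomes = NA_real_,
        filter_status = "PASS",
        median_gq = 60,
        median_depth = 40,
        allele_count = 5L,
        rule = rep(rules, length.out = n),
        stringsAsFactors = FALSE)
    if (!length(rules)) base <- base[0, , drop = FALSE]
    rules <- base$rule

    base$af_exomes[rules == "af_high"] <- 0.02
    base$consequence[rules == "not_missense"] <- "synonymous"
    base$gene[rules == "gene_no_pathogenic"] <- "GENE_NOPATH"
    base$clinical_label[rules == "vus"] <- "VUS"
    base$review_stars[rules == "zero_star"] <- 0L
    base$clinical_label[rules == "conflicting"] <- "conflicting"
    base$filter_status[rules == "fail_filter"] <- "RF"
    base$median_gq[rules == "low_gq"] <- 15
    base$median_depth[rules == "low_depth_rare"] <- 25
    base$allele_count[rules == "low_depth_rare"] <- 2L
    ## region-violating records sit in a dedicated window
    base$pos[rules == "region"] <- 50000L + seq_len(sum(rules == "region"))
    key <- paste(base$chrom, base$pos, base$ref, base$alt, sep = ":")
    trainingKeys <- key[rules == "training"]
    excludeKeys <- key[rules == "labeled_overlap"]

    config <- filterConfig(
        afMax = 0.01, pathogenicGenes = "GENE_OK",
        trainingKeys = if (length(trainingKeys)) trainingKeys else NULL,
        excludeKeys = if (length(excludeKeys)) excludeKeys else NULL,
        excludeRegions = if (mode == "population")
            data.frame(chrom = "chr1", start = 49999L, end = 51000L)
        else NULL)
    list(records = base, expected = base[rules == "clean", , drop = FALSE],
         config = config,
         regions = if (mode == "population")
             data.frame(chrom = "chr1", start = 49999L, end = 51000L)
         else NULL)
}
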