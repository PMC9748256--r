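## Bayesian adaptation of the ACMG/AMP evidence framework: odds algebra,
## exponential evidence combination, cutoff tables, the c-solver and the
## points mapping.

#' Prior odds of pathogenicity
#'
#' Converts a prior probability of pathogenicity into prior odds,
#' `p / (1 - p)`.
#'
#' @param prior probability in (0, 1).
#' @return positive numeric odds.
#' @examples
#' priorOdds(0.0441)   # 0.0461 to 4 decimals
#' @export
priorOdds <- function(prior) {
    if (!is.numeric(prior) || any(is.na(prior)) ||
        any(prior <= 0) || any(prior >= 1))
        stop("'prior' must lie strictly inside (0, 1)")
    prior / (1 - prior)
}

#' Combined positive likelihood ratio of multiple evidence lines
#'
#' The exponential evidence model: `nVS` very strong, `nST` strong, `nMO`
#' moderate and `nSU` supporting lines of evidence combine to a positive
#' likelihood ratio of `c ^ (nVS + nST/2 + nMO/4 + nSU/8)`.  For the benign
#' direction the reciprocal is returned.
#'
#' @param nVS,nST,nMO,nSU non-negative integer counts of evidence lines.
#' @param c scaling constant, greater than 1.
#' @param direction `"pathogenic"` (default) or `"benign"`.
#' @return positive numeric likelihood ratio.
#' @examples
#' combinedLR(nSU = 1, c = 1124)             # 2.406, one supporting line
#' combinedLR(nSU = 2, nMO = 1, c = 1124)    # equals one strong line
#' @export
combinedLR <- function(nVS = 0, nST = 0, nMO = 0, nSU = 0, c,
                       direction = c("pathogenic", "benign")) {
    direction <- match.arg(direction)
    counts <- c(nVS, nST, nMO, nSU)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("evidence counts must be non-negative integers")
    if (!is.numeric(c) || length(c) != 1L || c <= 1)
        stop("'c' must be a single value > 1")
    lr <- c^(nVS + nST / 2 + nMO / 4 + nSU / 8)
    if (direction == "benign") 1 / lr else lr
}

#' Posterior probability of pathogenicity from a likelihood ratio
#'
#' `P = lr * p / ((lr - 1) * p + 1)`, the Bayes update of the prior `p` by a
#' (local or global) positive likelihood ratio.  Strictly increasing in both
#' arguments.  [lrFromPosterior()] is the exact inverse.
#'
#' @param lr positive likelihood ratio (vectorized; `Inf` gives posterior 1).
#' @param prior prior probability of pathogenicity in (0, 1).
#' @return posterior probability in `[0, 1]`.
#' @examples
#' posteriorFromLR(2.406, 0.0441)   # 0.0999
#' posteriorFromLR(33.53, 0.0441)   # 0.6073
#' @export
posteriorFromLR <- function(lr, prior) {
    if (any(lr < 0, na.rm = TRUE)) stop("'lr' must be positive")
    priorOdds(prior)  # validates prior
    out <- lr * prior / ((lr - 1) * prior + 1)
    out[is.infinite(lr)] <- 1
    out
}

#' @rdname posteriorFromLR
#' @param posterior posterior probability in `[0, 1]`.
#' @export
lrFromPosterior <- function(posterior, prior) {
    if (any(posterior < 0 | posterior > 1, na.rm = TRUE))
        stop("'posterior' must lie in [0, 1]")
    odds <- posterior / (1 - posterior)   # Inf at posterior 1
    odds / priorOdds(prior)
}

.cutoffTable <- function(prior, c) {
    exponents <- c(supporting = 1 / 8, moderate = 1 / 4,
                   strong = 1 / 2, very_strong = 1)
    lrPath <- c^exponents
    data.frame(
        criterion = rep(c("PP3", "BP4"), each = 4L),
        strength = rep(.STRENGTHS, 2L),
        direction = rep(.DIRECTIONS, each = 4L),
        lr_cutoff = c(lrPath, 1 / lrPath),
        lr_reciprocal = c(1 / lrPath, lrPath),
        ## benign posterior reported as probability of benignity
        posterior_cutoff = c(posteriorFromLR(lrPath, prior),
                             1 - posteriorFromLR(1 / lrPath, prior)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct an evidence configuration
#'
#' Builds the full table of per-strength likelihood-ratio and posterior
#' cutoffs from a prior probability and scaling constant.  Defaults are the
#' framework's reference configuration: prior 0.0441 with `c = 1124`, under
#' which a single supporting line corresponds to lr+ 2.406, moderate to
#' 5.790, strong to 33.53 and very strong to 1124, with benign cutoffs the
#' exact reciprocals.
#'
#' `strengthCutoffTable()` is an alias emphasising the table-building role.
#'
#' @param prior prior probability of pathogenicity in (0, 1).
#' @param c scaling constant > 1.
#' @return an [EvidenceConfig-class].
#' @examples
#' evidenceConfig(0.0441, 1124)
#' @export
evidenceConfig <- function(prior = 0.0441, c = 1124) {
    if (!is.numeric(prior) || length(prior) != 1L || prior <= 0 || prior >= 1)
        stop("'prior' must be a single probability in (0, 1)")
    if (!is.numeric(c) || length(c) != 1L || c <= 1)
        stop("'c' must be a single value > 1")
    new("EvidenceConfig", prior = prior, c = c,
        cutoffs = .cutoffTable(prior, c))
}

#' @rdname evidenceConfig
#' @export
strengthCutoffTable <- evidenceConfig

#' @describeIn EvidenceConfig-class prior probability of pathogenicity.
#' @export
setMethod("priorProb", "EvidenceConfig", function(x) x@prior)

#' @describeIn EvidenceConfig-class the scaling constant `c`.
#' @export
setMethod("scalingConstant", "EvidenceConfig", function(x) x@c)

#' @describeIn EvidenceConfig-class named lr+ cutoffs for one direction.
#' @export
setMethod("lrCutoffs", "EvidenceConfig", function(x, direction = "pathogenic") {
    direction <- match.arg(direction, .DIRECTIONS)
    sub <- x@cutoffs[x@cutoffs$direction == direction, ]
    setNames(sub$lr_cutoff, sub$strength)
})

#' @describeIn EvidenceConfig-class named posterior cutoffs for one
#'   direction (benign as probability of benignity).
#' @export
setMethod("posteriorCutoffs", "EvidenceConfig",
    function(x, direction = "pathogenic") {
    direction <- match.arg(direction, .DIRECTIONS)
    sub <- x@cutoffs[x@cutoffs$direction == direction, ]
    setNames(sub$posterior_cutoff, sub$strength)
})

#' @describeIn EvidenceConfig-class cutoff table as a data.frame.
#' @param x an [EvidenceConfig-class].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "EvidenceConfig", function(x, ...) x@cutoffs)

setMethod("show", "EvidenceConfig", function(object) {
    cat(sprintf("EvidenceConfig: prior = %.4g (odds %.4g), c = %.4g\n",
                object@prior, priorOdds(object@prior), object@c))
    tab <- object@cutoffs
    tab$lr_cutoff <- signif(tab$lr_cutoff, 4)
    tab$lr_reciprocal <- signif(tab$lr_reciprocal, 4)
    tab$posterior_cutoff <- signif(tab$posterior_cutoff, 4)
    print(tab, row.names = FALSE)
})

#' Solve for the scaling constant c over a set of rule constraints
#'
#' Returns the smallest value of `c` on `grid` for which every constraint is
#' satisfied.  A constraint is a list with a `combination` (named counts
#' `nVS`, `nST`, `nMO`, `nSU`) and either `posteriorFloor` (the combination's
#' posterior must reach at least this value) or `posteriorCeiling`.
#'
#' The shipped [defaultRuleConstraints()] encode the standard ACMG/AMP
#' combining rules ("likely pathogenic" combinations must reach posterior
#' 0.9, "pathogenic" combinations 0.99).  They are a reconstruction: the rule
#' list behind any published constant is a modelling choice, and several
#' classical combinations (e.g. two strong lines for pathogenic) are
#' individually much more demanding than others, so the solved value depends
#' strongly on which rules are included.  For this reason the reference
#' configuration accepts `c` as a constant rather than deriving it from the
#' solver.
#'
#' @param prior prior probability of pathogenicity.
#' @param constraints list of rule constraints (default
#'   [defaultRuleConstraints()]).
#' @param grid numeric vector of candidate `c` values, scanned in increasing
#'   order.
#' @return the smallest feasible `c`, or `NA` (with a message) when no grid
#'   value satisfies all constraints.
#' @examples
#' ## one very strong line must reach posterior 0.99 at prior 0.10:
#' ## closed form c = 99 * (1 - p) / p = 891
#' solveC(0.10, list(list(combination = c(nVS = 1), posteriorFloor = 0.99)),
#'        grid = seq(100, 2000, by = 1))
#' @export
solveC <- function(prior, constraints = defaultRuleConstraints(),
                   grid = seq(2, 5000, by = 1)) {
    if (!length(constraints)) stop("'constraints' must be non-empty")
    grid <- sort(grid)
    ok <- rep(TRUE, length(grid))
    for (ct in constraints) {
        comb <- as.list(ct$combination)
        lr <- vapply(grid, function(cc)
            combinedLR(nVS = comb$nVS %||% 0, nST = comb$nST %||% 0,
                       nMO = comb$nMO %||% 0, nSU = comb$nSU %||% 0,
                       c = cc), numeric(1))
        post <- posteriorFromLR(lr, prior)
        if (!is.null(ct$posteriorFloor))
            ok <- ok & post >= ct$posteriorFloor
        if (!is.null(ct$posteriorCeiling))
            ok <- ok & post <= ct$posteriorCeiling
    }
    if (!any(ok)) {
        message("no grid value of c satisfies all constraints")
        return(NA_real_)
    }
    grid[which(ok)[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default ACMG/AMP combining-rule constraints
#'
#' The 2015 ACMG/AMP Table-5 evidence combinations, expressed as posterior
#' floors: combinations that classify a variant as likely pathogenic must
#' reach posterior 0.9 and combinations that classify it as pathogenic must
#' reach 0.99.  Stand-alone and BA1-type rules are outside the PP3/BP4
#' algebra and are not represented.
#'
#' @return list of constraints consumable by [solveC()].
#' @export
defaultRuleConstraints <- function() {
    lp <- list(c(nVS = 1, nMO = 1), c(nST = 1, nMO = 1), c(nST = 1, nMO = 2),
               c(nST = 1, nSU = 2), c(nMO = 3), c(nMO = 2, nSU = 2),
               c(nMO = 1, nSU = 4))
    p <- list(c(nVS = 1, nST = 1), c(nVS = 1, nMO = 2),
              c(nVS = 1, nMO = 1, nSU = 1), c(nVS = 1, nSU = 2),
              c(nST = 2), c(nST = 1, nMO = 3), c(nST = 1, nMO = 2, nSU = 2),
              c(nST = 1, nMO = 1, nSU = 4))
    c(lapply(lp, function(x) list(combination = x, posteriorFloor = 0.90)),
      lapply(p, function(x) list(combination = x, posteriorFloor = 0.99)))
}

#' Points value of an evidence strength
#'
#' The points-based rendering of the exponential model: log2 of the evidence
#' exponent weights, i.e. supporting = 1, moderate = 2, strong = 4, very
#' strong = 8 points, signed negative in the benign direction (a moderate
#' benign call contributes -2 points).
#'
#' @param strength one of `"supporting"`, `"moderate"`, `"strong"`,
#'   `"very_strong"` (vectorized).
#' @param direction `"pathogenic"` or `"benign"` (vectorized, recycled).
#' @return signed integer points.
#' @examples
#' pointsValue("moderate", "benign")        # -2
#' pointsValue("very_strong", "pathogenic") # +8
#' @export
pointsValue <- function(strength, direction = "pathogenic") {
    pts <- c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L)
    if (!all(strength %in% names(pts))) stop("unknown strength")
    if (!all(direction %in% .DIRECTIONS)) stop("unknown direction")
    sign <- ifelse(direction == "benign", -1L, 1L)
    unname(pts[strength] * sign)
}
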