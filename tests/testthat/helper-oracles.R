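## Independent definition-level implementations used as oracles: explicit
## loops over candidate windows, quadratic threshold scans and a per-record
## filter evaluator.  They share no code with the package's compiled path.

## Local posterior curve by direct enumeration: for every unique labeled
## score, scan candidate half-widths (observed distances) until the scaled
## requirements hold, then count classes in the closed window.
bruteCurve <- function(pathScores, benScores, unlabeled = numeric(),
                       minLabeled, minUnlabeledFrac = 0, weight = 1,
                       edgeScaling = c("proportional", "none")) {
    edgeScaling <- match.arg(edgeScaling)
    lab <- c(pathScores, benScores)
    grid <- sort(unique(lab))
    rng <- range(c(lab, unlabeled))
    minUnl <- minUnlabeledFrac * length(unlabeled)
    eps <- post <- numeric(length(grid))
    for (t in seq_along(grid)) {
        s <- grid[t]
        dLab <- abs(lab - s)
        dUnl <- abs(unlabeled - s)
        found <- NA_real_
        for (e in sort(unique(c(0, dLab, dUnl)))) {
            f <- if (edgeScaling == "proportional" && e > 0)
                (min(s + e, rng[2]) - max(s - e, rng[1])) / (2 * e) else 1
            if (sum(dLab <= e) + 1e-9 >= minLabeled * f &&
                (minUnl <= 0 || sum(dUnl <= e) + 1e-9 >= minUnl * f)) {
                found <- e
                break
            }
        }
        if (is.na(found)) stop("oracle: requirements unsatisfiable")
        eps[t] <- found
        P <- sum(abs(pathScores - s) <= found)
        B <- sum(abs(benScores - s) <= found)
        post[t] <- P / (P + weight * B)
    }
    list(score = grid, epsilon = eps, posterior = post)
}

## Threshold by checking every suffix (pathogenic) / prefix (benign)
## explicitly against the cutoff.
bruteSelectThreshold <- function(score, bound, postCutoff,
                                 direction = c("pathogenic", "benign")) {
    direction <- match.arg(direction)
    n <- length(score)
    if (direction == "pathogenic") {
        for (i in seq_len(n))
            if (all(bound[i:n] >= postCutoff)) return(score[i])
        return(NA_real_)
    }
    res <- NA_real_
    for (i in seq_len(n))
        if (all(bound[1:i] <= postCutoff)) res <- score[i]
    res
}

## Per-record rule evaluation for the labeled-set filter (ignores ordering:
## a record survives iff it violates no rule).
bruteLabeledSurvivors <- function(records, config) {
    ok <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        af <- if (!is.na(r$af_exomes)) r$af_exomes else r$af_genomes
        key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
        ok[i] <- r$consequence == "missense" &&
            (is.na(af) || af < config$afMax) &&
            (is.null(config$pathogenicGenes) ||
                 r$gene %in% config$pathogenicGenes) &&
            !(r$clinical_label %in% c("VUS", "conflicting")) &&
            r$review_stars >= 1 &&
            !(key %in% config$trainingKeys) &&
            !(key %in% config$excludeKeys)
    }
    records[ok, , drop = FALSE]
}

brutePopulationSurvivors <- function(records, config) {
    ok <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        af <- if (!is.na(r$af_exomes)) r$af_exomes else r$af_genomes
        key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
        needDP <- if (r$allele_count < config$depthRule$acBreak)
            config$depthRule$dpLowAC else config$depthRule$dpHighAC
        inRegion <- FALSE
        if (!is.null(config$excludeRegions)) {
            bed <- config$excludeRegions
            for (j in seq_len(nrow(bed)))
                if (r$chrom == bed$chrom[j] && r$pos > bed$start[j] &&
                    r$pos <= bed$end[j]) inRegion <- TRUE
        }
        ok[i] <- (is.na(af) || af < config$afMax) &&
            r$filter_status == "PASS" && r$median_gq > config$minGQ &&
            r$median_depth >= needDP &&
            r$consequence == "missense" &&
            (is.null(config$pathogenicGenes) ||
                 r$gene %in% config$pathogenicGenes) &&
            !inRegion && !(key %in% config$trainingKeys) &&
            !(key %in% config$excludeKeys)
    }
    records[ok, , drop = FALSE]
}

## Small labeled-data builder shared by several tests.
makeLabeled <- function(pathScores, benScores) {
    n <- length(pathScores) + length(benScores)
    data.frame(variant_key = sprintf("v%05d", seq_len(n)),
               score = c(pathScores, benScores),
               label = rep(c("P", "B"),
                           c(length(pathScores), length(benScores))),
               stringsAsFactors = FALSE)
}

calibrateRaw <- function(pathScores, benScores, unlabeled = numeric(),
                         prior = 0.5, c = 1124, ...) {
    lab <- makeLabeled(pathScores, benScores)
    calibrateScores(lab[, c("variant_key", "score")],
                    lab[, c("variant_key", "label")], unlabeled,
                    config = evidenceConfig(prior, c),
                    settings = calibrationSettings(...))
}
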