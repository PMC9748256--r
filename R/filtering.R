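## Generic filter engine for assembling calibration data sets from tabular
## variant records: clinical-archive (labeled) rules and population-database
## rules, each emitting a per-step waterfall of surviving counts.

#' Filter configuration
#'
#' @param afMax allele-frequency ceiling (variants at or above it are
#'   dropped; default 0.01).  The exomes AF is consulted first and the
#'   genomes AF used as fallback; variants absent from both are treated as
#'   rare and retained.
#' @param pathogenicGenes character vector of gene symbols with at least one
#'   pathogenic variant of any type; `NULL` disables the gene step.
#' @param trainingKeys character vector of variant keys present in any
#'   tool's training set (constituent tools of meta-predictors included by
#'   concatenation); `NULL` disables the step.
#' @param excludeKeys variant keys to remove (e.g. overlap with an earlier
#'   labeled snapshot); `NULL` disables.
#' @param excludeRegions regions whose variants are removed (segmental
#'   duplications, low-complexity, decoy): a `GRanges`, a data.frame with
#'   `chrom`/`start`/`end` in 0-based half-open BED convention, or a path to
#'   a BED file.  `NULL` disables.
#' @param minGQ median genotype quality floor (exclusive; default 20).
#' @param depthRule list with `acBreak`, `dpLowAC`, `dpHighAC`: variants
#'   need median depth >= `dpLowAC` when the allele count is below
#'   `acBreak`, and >= `dpHighAC` otherwise (defaults 3, 30, 10).
#' @param trainingLast apply the training-set step after all other steps
#'   (the ordering used for held-out validation snapshots) instead of in its
#'   default position.
#' @return a list of filter settings.
#' @export
filterConfig <- function(afMax = 0.01, pathogenicGenes = NULL,
                         trainingKeys = NULL, excludeKeys = NULL,
                         excludeRegions = NULL, minGQ = 20,
                         depthRule = list(acBreak = 3, dpLowAC = 30,
                                          dpHighAC = 10),
                         trainingLast = FALSE) {
    stopifnot(afMax > 0, afMax <= 1)
    list(afMax = afMax, pathogenicGenes = pathogenicGenes,
         trainingKeys = trainingKeys, excludeKeys = excludeKeys,
         excludeRegions = excludeRegions, minGQ = minGQ,
         depthRule = depthRule, trainingLast = trainingLast)
}

## effective allele frequency: exomes first, genomes fallback, missing = rare
.effectiveAF <- function(records) {
    af <- records$af_exomes
    if (is.null(af)) af <- rep(NA_real_, nrow(records))
    if (!is.null(records$af_genomes)) {
        use <- is.na(af)
        af[use] <- records$af_genomes[use]
    }
    af
}

.variantKey <- function(records) {
    if (!is.null(records$variant_key)) return(records$variant_key)
    paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

.dropIncomplete <- function(records, fields, step) {
    need <- intersect(fields, names(records))
    if (!length(need)) return(records)
    bad <- rowSums(is.na(records[, need, drop = FALSE])) > 0
    if (any(bad))
        warning(sprintf("dropping %d record(s) with missing %s fields",
                        sum(bad), step))
    records[!bad, , drop = FALSE]
}

.regionGRanges <- function(x) {
    if (is(x, "GRanges")) return(x)
    if (is.character(x) && length(x) == 1L) {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("reading BED files requires the rtracklayer package")
        out <- tryCatch(rtracklayer::import(x, format = "BED"),
                        error = function(e)
                            stop("malformed BED file: ", conditionMessage(e)))
        return(out)
    }
    if (is.data.frame(x)) {
        if (!all(c("chrom", "start", "end") %in% names(x)))
            stop("region data.frame needs chrom/start/end (BED convention)")
        ## BED is 0-based half-open; GRanges is 1-based closed
        return(GenomicRanges::GRanges(
            x$chrom, IRanges::IRanges(x$start + 1L, x$end)))
    }
    stop("'excludeRegions' must be a GRanges, BED data.frame or BED path")
}

.inRegions <- function(records, regions) {
    gr <- GenomicRanges::GRanges(
        records$chrom,
        IRanges::IRanges(records$pos,
                         records$pos + nchar(as.character(records$ref)) - 1L))
    GenomicRanges::countOverlaps(gr, regions) > 0
}

.waterfall <- function(steps, counts) {
    data.frame(step = steps, surviving = counts, row.names = NULL)
}

#' Filter a labeled (clinical-archive) variant set
#'
#' Applies, in order: keep missense variants with effective allele frequency
#' below `afMax`; keep variants from genes with at least one pathogenic
#' variant; drop variants of uncertain significance, zero-star review status
#' and conflicting classifications; drop tool-training-set members (last of
#' all steps when `trainingLast`); drop explicitly excluded keys.  Records
#' missing a field a step requires are dropped with a warning.
#'
#' Expected columns: `chrom`, `pos`, `ref`, `alt` (or a precomputed
#' `variant_key`), `gene`, `clinical_label` (P/LP/B/LB/VUS/conflicting/
#' none), `review_stars`, `consequence`, `af_exomes`, `af_genomes`.
#'
#' @param records data.frame of variant records.
#' @param config a [filterConfig()].
#' @return list with `records` (survivors) and `waterfall` (data.frame of
#'   per-step surviving counts).
#' @export
filterLabeledSet <- function(records, config = filterConfig()) {
    steps <- character()
    counts <- integer()
    note <- function(step, recs) {
        steps <<- c(steps, step)
        counts <<- c(counts, nrow(recs))
        recs
    }
    r <- note("input", records)
    if (nrow(r)) {
        r <- .dropIncomplete(r, "consequence", "consequence")
        af <- .effectiveAF(r)
        r <- r[r$consequence == "missense" & (is.na(af) | af < config$afMax),
               , drop = FALSE]
    }
    r <- note("missense_af", r)
    if (!is.null(config$pathogenicGenes)) {
        if (nrow(r)) {
            r <- .dropIncomplete(r, "gene", "gene")
            r <- r[r$gene %in% config$pathogenicGenes, , drop = FALSE]
        }
        r <- note("gene_has_pathogenic", r)
    }
    if (nrow(r)) {
        r <- .dropIncomplete(r, c("clinical_label", "review_stars"),
                             "review")
        keep <- !(r$clinical_label %in% c("VUS", "conflicting")) &
            r$review_stars >= 1
        r <- r[keep, , drop = FALSE]
    }
    r <- note("drop_vus_zero_star_conflicting", r)
    applyTraining <- function(r) {
        if (is.null(config$trainingKeys)) return(r)
        r <- r[!(.variantKey(r) %in% config$trainingKeys), , drop = FALSE]
        note("drop_training_members", r)
    }
    applyExclude <- function(r) {
        if (is.null(config$excludeKeys)) return(r)
        r <- r[!(.variantKey(r) %in% config$excludeKeys), , drop = FALSE]
        note("drop_excluded_keys", r)
    }
    if (config$trainingLast) {
        r <- applyExclude(r)
        r <- applyTraining(r)
    } else {
        r <- applyTraining(r)
        r <- applyExclude(r)
    }
    list(records = r, waterfall = .waterfall(steps, counts))
}

#' Filter a population (reference-database) variant set
#'
#' Applies, in order: effective allele frequency below `afMax`; `FILTER`
#' status `"PASS"`; median genotype quality above `minGQ`; the
#' allele-count-conditional depth rule (depth >= `dpLowAC` when the allele
#' count is below `acBreak`, else >= `dpHighAC`); missense consequence from
#' genes with a pathogenic variant; union of the exome and genome tables
#' deduplicated by variant key; removal of variants in excluded regions
#' (segmental duplications / low-complexity / decoy), of training-set
#' members and of variants present in the labeled archive (`excludeKeys`).
#'
#' Additional expected columns over [filterLabeledSet()]: `filter_status`,
#' `median_gq`, `median_depth`, `allele_count`.
#'
#' @param exomes data.frame of exome-derived records.
#' @param genomes optional data.frame of genome-derived records, merged with
#'   the exomes by variant-key union after the quality steps.
#' @param config a [filterConfig()].
#' @return list with `records` and `waterfall`.
#' @export
filterPopulationSet <- function(exomes, genomes = NULL,
                                config = filterConfig()) {
    steps <- character()
    counts <- integer()
    note <- function(step, recs) {
        steps <<- c(steps, step)
        counts <<- c(counts, nrow(recs))
        recs
    }
    tabs <- if (is.null(genomes)) list(exomes)
            else list(exomes, genomes)
    stepBoth <- function(step, f) {
        tabs <<- lapply(tabs, f)
        steps <<- c(steps, step)
        counts <<- c(counts, sum(vapply(tabs, nrow, integer(1))))
    }
    steps <- c(steps, "input")
    counts <- c(counts, sum(vapply(tabs, nrow, integer(1))))
    stepBoth("allele_frequency", function(r) {
        if (!nrow(r)) return(r)
        af <- .effectiveAF(r)
        r[is.na(af) | af < config$afMax, , drop = FALSE]
    })
    stepBoth("pass_and_gq", function(r) {
        if (!nrow(r)) return(r)
        r <- .dropIncomplete(r, c("filter_status", "median_gq"), "quality")
        r[r$filter_status == "PASS" & r$median_gq > config$minGQ, ,
          drop = FALSE]
    })
    stepBoth("depth_by_allele_count", function(r) {
        if (!nrow(r)) return(r)
        r <- .dropIncomplete(r, c("median_depth", "allele_count"), "depth")
        dr <- config$depthRule
        needDP <- ifelse(r$allele_count < dr$acBreak, dr$dpLowAC,
                         dr$dpHighAC)
        r[r$median_depth >= needDP, , drop = FALSE]
    })
    stepBoth("missense_pathogenic_gene", function(r) {
        if (!nrow(r)) return(r)
        r <- .dropIncomplete(r, "consequence", "consequence")
        r <- r[r$consequence == "missense", , drop = FALSE]
        if (!is.null(config$pathogenicGenes))
            r <- r[r$gene %in% config$pathogenicGenes, , drop = FALSE]
        r
    })
    r <- do.call(rbind, tabs)
    if (nrow(r))
        r <- r[!duplicated(.variantKey(r)), , drop = FALSE]
    r <- note("union_dedup", r)
    if (!is.null(config$excludeRegions)) {
        regions <- .regionGRanges(config$excludeRegions)
        if (nrow(r)) r <- r[!.inRegions(r, regions), , drop = FALSE]
        r <- note("drop_excluded_regions", r)
    }
    if (!is.null(config$trainingKeys)) {
        r <- r[!(.variantKey(r) %in% config$trainingKeys), , drop = FALSE]
        r <- note("drop_training_members", r)
    }
    if (!is.null(config$excludeKeys)) {
        r <- r[!(.variantKey(r) %in% config$excludeKeys), , drop = FALSE]
        r <- note("drop_labeled_overlap", r)
    }
    list(records = r, waterfall = .waterfall(steps, counts))
}
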