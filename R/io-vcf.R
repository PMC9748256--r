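## VCF ingestion: thin wrapper turning a VCF into the tabular variant-record
## layout the filter engine and score joiners consume.

#' Read variant records from a VCF file
#'
#' Expands multi-allelic rows and returns one record per alternate allele
#' with a `chrom:pos:ref:alt` variant key.  Requested INFO fields are
#' flattened into columns (first element kept for per-allele lists), so
#' clinical significance, review status or allele-frequency annotations can
#' be carried into [filterLabeledSet()] / [filterPopulationSet()] after
#' renaming to the engine's column names.
#'
#' Requires the VariantAnnotation package.
#'
#' @param path path to a VCF file.
#' @param info character vector of INFO fields to keep (default all).
#' @return data.frame with `variant_key`, `chrom`, `pos`, `ref`, `alt`,
#'   `filter_status` and one column per kept INFO field.
#' @export
readVcfRecords <- function(path, info = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("reading VCF files requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    gr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(alt)
    idx <- rep(seq_along(gr), nAlt)
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr))[idx],
        pos = GenomicRanges::start(gr)[idx],
        ref = as.character(VariantAnnotation::ref(vcf))[idx],
        alt = as.character(unlist(alt)),
        filter_status = as.character(VariantAnnotation::filt(vcf))[idx],
        stringsAsFactors = FALSE)
    out$variant_key <- paste(out$chrom, out$pos, out$ref, out$alt,
                             sep = ":")
    infoDf <- VariantAnnotation::info(vcf)
    keep <- if (is.null(info)) colnames(infoDf)
            else intersect(info, colnames(infoDf))
    for (field in keep) {
        v <- infoDf[[field]]
        if (is(v, "List")) {
            first <- vapply(as.list(v), function(el)
                if (length(el)) as.character(el[[1L]]) else NA_character_,
                character(1))
            out[[field]] <- first[idx]
        } else {
            out[[field]] <- v[idx]
        }
    }
    out[, c("variant_key", setdiff(names(out), "variant_key")),
        drop = FALSE]
}
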