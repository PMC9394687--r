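#' One-transcript gene model
#'
#' A transcript's CDS as ordered genomic intervals (1-based, inclusive, the
#' R/Bioconductor convention, matching the on-disk dialect). One canonical
#' transcript per gene is required so codon numbering is unambiguous.
#'
#' @slot gene gene symbol.
#' @slot txId transcript identifier.
#' @slot chrom sequence name.
#' @slot strand "+" or "-".
#' @slot exons \code{IRanges} of CDS exons, sorted by genomic position,
#'   non-overlapping, total width divisible by 3.
#' @export
setClass("TranscriptModel", representation(
    gene = "character", txId = "character", chrom = "character",
    strand = "character", exons = "IRanges"))

setValidity("TranscriptModel", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex)) {
        if (is.unsorted(BiocGenerics::start(ex)))
            msg <- c(msg, "exons must be sorted by genomic position")
        if (length(ex) > 1L &&
            any(BiocGenerics::start(ex)[-1L] <=
                BiocGenerics::end(ex)[-length(ex)]))
            msg <- c(msg, "exons must not overlap")
        if (sum(BiocGenerics::width(ex)) %% 3L != 0L)
            msg <- c(msg, "total CDS length must be divisible by 3")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname TranscriptModel-class
#' @param gene,txId,chrom,strand scalars; see slots.
#' @param starts,ends 1-based inclusive CDS exon coordinates.
#' @export
TranscriptModel <- function(gene, txId, chrom, strand, starts, ends) {
    starts <- as.integer(starts); ends <- as.integer(ends)
    if (any(ends < starts))
        stop("transcript ", txId, ": CDS exon with end < start")
    o <- order(starts)
    new("TranscriptModel", gene = gene, txId = txId, chrom = chrom,
        strand = strand, exons = IRanges(starts[o], ends[o]))
}

#' @rdname TranscriptModel-class
#' @param x a \code{TranscriptModel}.
#' @export
cdsLength <- function(x) sum(BiocGenerics::width(x@exons))

#' @rdname TranscriptModel-class
#' @export
nCodons <- function(x) cdsLength(x) %/% 3L

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (%s) %s%s, %d CDS exon(s), %d codons\n",
                object@txId, object@gene, object@chrom, object@strand,
                length(object@exons), nCodons(object)))
})

#' Read gene models from the package's TSV dialect
#'
#' Tab-separated columns: \code{gene}, \code{transcript}, \code{chrom},
#' \code{strand} (+/-), \code{cds_starts} (comma list, 1-based),
#' \code{cds_ends} (comma list, inclusive). One row per transcript, one
#' canonical transcript per gene.
#'
#' @param path TSV file.
#' @return named list of \linkS4class{TranscriptModel} (names = gene).
#' @seealso \code{\link{writeGeneModels}}
#' @export
readGeneModels <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene", "transcript", "chrom", "strand", "cds_starts",
              "cds_ends")
    if (!all(need %in% names(tab)))
        stop("gene-model file must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene))
        stop("one canonical transcript per gene required; duplicated: ",
             paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
    txs <- lapply(seq_len(nrow(tab)), function(i) {
        starts <- as.integer(strsplit(tab$cds_starts[i], ",")[[1]])
        ends <- as.integer(strsplit(tab$cds_ends[i], ",")[[1]])
        if (length(starts) != length(ends))
            stop("transcript ", tab$transcript[i],
                 ": cds_starts/cds_ends length mismatch")
        if (any(ends < starts))
            stop("transcript ", tab$transcript[i],
                 ": CDS exon with end < start")
        if (sum(ends - starts + 1L) %% 3L != 0L)
            stop("transcript ", tab$transcript[i],
                 ": CDS length not divisible by 3")
        TranscriptModel(tab$gene[i], tab$transcript[i], tab$chrom[i],
                        tab$strand[i], starts, ends)
    })
    names(txs) <- tab$gene
    txs
}

#' Write gene models in the package's TSV dialect
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(transcripts, path) {
    rows <- vapply(transcripts, function(tx) {
        paste(tx@gene, tx@txId, tx@chrom, tx@strand,
              paste(BiocGenerics::start(tx@exons), collapse = ","),
              paste(BiocGenerics::end(tx@exons), collapse = ","),
              sep = "\t")
    }, character(1))
    writeLines(c("gene\ttranscript\tchrom\tstrand\tcds_starts\tcds_ends",
                 rows), path)
    invisible(path)
}
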