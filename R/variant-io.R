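#' Read a multi-sample screen VCF into a CloneScreenPanel
#'
#' Reads a VCF 4.x (as produced by GATK HaplotypeCaller for a jointly
#' genotyped screen) and maps samples to screen roles. Multi-allelic sites
#' are decomposed into biallelic records with allele-specific depths; indels
#' are reduced to minimal representation (shared suffix, then shared prefix,
#' trimmed) before keying so set operations compare like with like. Samples
#' without a genotype at a site are kept as uncalled placeholders. Missing
#' INFO/FORMAT values become \code{NA}, distinguishable from 0.
#'
#' @param path VCF file.
#' @param parental parental sample name (must be in the VCF header).
#' @param clones resistant clone sample names.
#' @param counterScreen counter-screen sample names.
#' @return A \linkS4class{CloneScreenPanel}.
#' @seealso \code{\link{writeScreenVcf}}
#' @export
readScreenVcf <- function(path, parental, clones, counterScreen = character()) {
    if (!file.exists(path))
        stop("VCF not found: ", path)
    vcf <- tryCatch(
        suppressWarnings(VariantAnnotation::readVcf(path)),
        error = function(e)
            stop("malformed VCF '", path, "': ", conditionMessage(e),
                 call. = FALSE))
    samples <- c(parental, clones, counterScreen)
    missing <- setdiff(samples, colnames(vcf))
    if (length(missing))
        stop("configuration error: sample(s) not in VCF header: ",
             paste(missing, collapse = ", "))
    vcf <- VariantAnnotation::expand(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    ok <- grepl("^[ACGTacgt]+$", ref) & grepl("^[ACGTacgt]+$", alt) & ref != alt
    if (!all(ok)) {
        warning(sum(!ok), " record(s) with symbolic/degenerate alleles dropped")
        vcf <- vcf[ok]
        ref <- ref[ok]; alt <- alt[ok]
    }
    gr <- SummarizedExperiment::rowRanges(vcf)
    norm <- normalizeVariants(as.character(GenomicRanges::seqnames(gr)),
                              GenomicRanges::start(gr),
                              toupper(ref), toupper(alt))

    infoOr <- function(field) {
        inf <- VariantAnnotation::info(vcf)
        if (field %in% names(inf)) as.numeric(inf[[field]])
        else rep(NA_real_, nrow(vcf))
    }
    variants <- data.frame(chrom = norm$chrom, pos = norm$pos,
                           ref = norm$ref, alt = norm$alt,
                           qd = infoOr("QD"), fs = infoOr("FS"),
                           mq = infoOr("MQ"))

    g <- VariantAnnotation::geno(vcf)
    n <- nrow(vcf)
    emptyInt <- function() matrix(NA_integer_, n, length(samples),
                                  dimnames = list(NULL, samples))
    refDepth <- emptyInt(); altDepth <- emptyInt()
    if ("AD" %in% names(g)) {
        ad <- g$AD   # variants x samples x 2 after expand()
        refDepth[] <- ad[, samples, 1, drop = FALSE]
        altDepth[] <- ad[, samples, 2, drop = FALSE]
    }
    depth <- if ("DP" %in% names(g)) {
        m <- g$DP[, samples, drop = FALSE]; storage.mode(m) <- "integer"; m
    } else emptyInt()
    gq <- if ("GQ" %in% names(g)) {
        m <- g$GQ[, samples, drop = FALSE]; storage.mode(m) <- "integer"; m
    } else emptyInt()
    called <- if ("GT" %in% names(g)) {
        gt <- g$GT[, samples, drop = FALSE]
        !(is.na(gt) | gt %in% c(".", "./.", ".|."))
    } else !is.na(depth) & depth > 0L

    if (n == 1L) {  # drop=FALSE above keeps arrays, but guard dimnames
        dimnames(refDepth) <- list(NULL, samples)
        dimnames(altDepth) <- list(NULL, samples)
    }
    panel <- CloneScreenPanel(variants, refDepth = refDepth,
                              altDepth = altDepth, depth = depth, gq = gq,
                              called = called, parental = parental,
                              clones = clones, counterScreen = counterScreen)
    metadata(panel)$source <- path
    panel
}

#' Reduce variants to minimal representation
#'
#' Trims the shared suffix, then the shared prefix (advancing \code{pos}), of
#' each ref/alt pair, so that equivalent indel spellings get identical keys.
#'
#' @param chrom,pos,ref,alt parallel vectors describing variants.
#' @return list with normalized \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @export
normalizeVariants <- function(chrom, pos, ref, alt) {
    pos <- as.integer(pos)
    for (i in seq_along(ref)) {
        r <- ref[i]; a <- alt[i]; p <- pos[i]
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
            r <- substr(r, 1L, nchar(r) - 1L)
            a <- substr(a, 1L, nchar(a) - 1L)
        }
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
            r <- substr(r, 2L, nchar(r))
            a <- substr(a, 2L, nchar(a))
            p <- p + 1L
        }
        ref[i] <- r; alt[i] <- a; pos[i] <- p
    }
    list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Write a CloneScreenPanel as a multi-sample VCF
#'
#' Emits VCF 4.2 with INFO QD/FS/MQ and FORMAT GT:AD:DP:GQ. Genotypes are
#' reconstructed from the \code{called} assay (uncalled samples get
#' \code{./.}); re-reading with \code{\link{readScreenVcf}} recovers
#' identical variant keys, depths and site annotations.
#'
#' @param panel a \linkS4class{CloneScreenPanel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScreenVcf <- function(panel, path) {
    gr <- rowRanges(panel)
    mc <- mcols(gr)
    samples <- colnames(panel)
    rd <- assay(panel, "refDepth"); ad <- assay(panel, "altDepth")
    dp <- assay(panel, "depth"); gq <- assay(panel, "gq")
    called <- assay(panel, "called")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=ForwardScreen",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence/Quality by Depth\">",
        "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled p-value using Fisher's exact test to detect strand bias\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS Mapping Quality\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
        paste0("##contig=<ID=", unique(as.character(seqnames(gr))),
               ">"),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t")), con)
    num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%g", x))
    fields <- cbind(QD = num(mc$qd), FS = num(mc$fs), MQ = num(mc$mq))
    infoStr <- apply(fields, 1L, function(r) {
        r <- r[!is.na(r)]
        if (!length(r)) "." else
            paste(paste0(names(r), "=", r), collapse = ";")
    })
    intOr <- function(x) ifelse(is.na(x), ".", as.character(x))
    gt <- ifelse(!called, "./.",
          ifelse(!is.na(ad) & ad > 0L & !is.na(rd) & rd == 0L, "1/1",
          ifelse(!is.na(ad) & ad > 0L, "0/1", "0/0")))
    adStr <- ifelse(is.na(rd) & is.na(ad), ".",
                    paste0(intOr(rd), ",", intOr(ad)))
    cells <- matrix(paste(gt, adStr, intOr(dp), intOr(gq), sep = ":"),
                    nrow = nrow(panel))
    cells[!called] <- "./.:.:.:."
    chrom <- as.character(seqnames(gr))
    pos <- start(gr)
    lines <- do.call(paste, c(
        list(chrom, pos, ".", mc$ref, mc$alt, ".", ".", infoStr,
             "GT:AD:DP:GQ"),
        lapply(seq_along(samples), function(j) cells[, j]),
        sep = "\t"))
    writeLines(lines[order(chrom, pos, mc$ref, mc$alt)], con)
    invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return named \code{DNAStringSet}, uppercase, names taken from the first
#'   whitespace-delimited token of each header. An empty file yields an
#'   empty set with a warning.
#' @export
readReference <- function(path) {
    if (!file.exists(path))
        stop("reference FASTA not found: ", path)
    if (file.size(path) == 0L) {
        warning("reference FASTA is empty: ", path)
        return(Biostrings::DNAStringSet())
    }
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    Biostrings::DNAStringSet(toupper(as.character(seqs)))
}
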