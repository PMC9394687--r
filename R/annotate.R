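#' CDS offset of a genomic position
#'
#' 0-based offset of a genomic position among the coding bases of a
#' transcript, counted in transcription direction (offset 0 is the first base
#' of the start codon; on the minus strand that is the highest genomic
#' coordinate of the CDS). \code{NA} if the position is not in the CDS.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param pos 1-based genomic position.
#' @return integer offset or \code{NA}.
#' @export
cdsOffset <- function(tx, pos) {
    ex <- tx@exons
    s <- BiocGenerics::start(ex); e <- BiocGenerics::end(ex)
    w <- BiocGenerics::width(ex)
    idx <- which(pos >= s & pos <= e)
    if (!length(idx)) return(NA_integer_)
    before <- if (idx > 1L) sum(w[seq_len(idx - 1L)]) else 0L
    plusOff <- before + (pos - s[idx])
    if (tx@strand == "+") as.integer(plusOff)
    else as.integer(cdsLength(tx) - 1L - plusOff)
}

#' @rdname cdsOffset
#' @param offset 0-based CDS offset (transcription direction).
#' @return \code{cdsToGenomic}: the 1-based genomic position of that coding
#'   base.
#' @export
cdsToGenomic <- function(tx, offset) {
    ex <- tx@exons
    s <- BiocGenerics::start(ex)
    w <- BiocGenerics::width(ex)
    plusOff <- if (tx@strand == "+") offset else cdsLength(tx) - 1L - offset
    if (plusOff < 0L || plusOff >= cdsLength(tx))
        stop("CDS offset out of range: ", offset)
    cw <- cumsum(w)
    idx <- which(plusOff < cw)[1L]
    before <- if (idx > 1L) cw[idx - 1L] else 0L
    as.integer(s[idx] + (plusOff - before))
}

compBase <- function(x) chartr("ACGT", "TGCA", x)

splicePositions <- function(tx, window = 2L) {
    ex <- tx@exons
    if (length(ex) < 2L || window < 1L) return(integer())
    s <- BiocGenerics::start(ex); e <- BiocGenerics::end(ex)
    out <- integer()
    for (i in seq_len(length(ex) - 1L)) {
        intronStart <- e[i] + 1L
        intronEnd <- s[i + 1L] - 1L
        if (intronEnd < intronStart) next
        k <- min(window, intronEnd - intronStart + 1L)
        out <- c(out, intronStart:(intronStart + k - 1L),
                 (intronEnd - k + 1L):intronEnd)
    }
    unique(out)
}

refBaseAt <- function(seqChar, pos, n = 1L) substr(seqChar, pos, pos + n - 1L)

#' Classify a variant against a transcript
#'
#' Maps a normalized variant to a codon-resolution coding consequence. SNVs
#' inside the CDS are translated with the standard genetic code
#' (strand-aware); indels are \code{frameshift} when the length change is not
#' a multiple of 3, else \code{inframe_indel}, with the first affected codon
#' reported. SNVs landing in the first/last \code{spliceWindow} bases of an
#' intron are \code{splice} (canonical donor/acceptor footprint, default 2).
#' Everything else is \code{noncoding}. The variant's ref allele is checked
#' against the reference sequence; a mismatch is an error.
#'
#' @param chrom,pos,ref,alt the variant (minimal representation, plus
#'   strand).
#' @param tx a \linkS4class{TranscriptModel}.
#' @param refSeqs named character vector or \code{DNAStringSet} of reference
#'   sequences.
#' @param spliceWindow intronic bases flanking each CDS exon treated as
#'   splice sites.
#' @return one-row \code{data.frame}: gene, txId, codonIndex, refAa, altAa,
#'   consequence, substitution.
#' @export
classifyVariant <- function(chrom, pos, ref, alt, tx, refSeqs,
                            spliceWindow = 2L) {
    if (!is.character(refSeqs)) {
        if (!chrom %in% names(refSeqs))
            stop("sequence '", chrom, "' absent from reference")
        seqChar <- as.character(refSeqs[[chrom]])
    } else {
        if (!chrom %in% names(refSeqs))
            stop("sequence '", chrom, "' absent from reference")
        seqChar <- refSeqs[[chrom]]
    }
    res <- function(class, codonIndex = NA_integer_, refAa = NA_character_,
                    altAa = NA_character_, substitution = NA_character_) {
        data.frame(gene = tx@gene, txId = tx@txId, codonIndex = codonIndex,
                   refAa = refAa, altAa = altAa, consequence = class,
                   substitution = substitution, stringsAsFactors = FALSE)
    }
    if (chrom != tx@chrom) return(res("noncoding"))
    isSnv <- nchar(ref) == 1L && nchar(alt) == 1L
    if (isSnv) {
        off <- cdsOffset(tx, pos)
        if (!is.na(off)) {
            actual <- refBaseAt(seqChar, pos)
            if (actual != ref)
                stop("reference mismatch at ", chrom, ":", pos,
                     ": variant ref '", ref, "' vs reference '", actual, "'")
            ci <- off %/% 3L + 1L
            within <- off %% 3L
            codonOffs <- (ci - 1L) * 3L + 0:2
            gpos <- vapply(codonOffs, function(o) cdsToGenomic(tx, o),
                           integer(1))
            bases <- vapply(gpos, function(p) refBaseAt(seqChar, p),
                            character(1))
            if (tx@strand == "-") bases <- compBase(bases)
            refCodon <- paste(bases, collapse = "")
            altTx <- if (tx@strand == "-") compBase(alt) else alt
            altBases <- bases
            altBases[within + 1L] <- altTx
            altCodon <- paste(altBases, collapse = "")
            refAa <- unname(Biostrings::GENETIC_CODE[refCodon])
            altAa <- unname(Biostrings::GENETIC_CODE[altCodon])
            class <- if (refAa == altAa) "synonymous"
                     else if (altAa == "*") "nonsense"
                     else "missense"
            return(res(class, ci, refAa, altAa,
                       substitution = paste0(refAa, ci, altAa)))
        }
        if (pos %in% splicePositions(tx, spliceWindow))
            return(res("splice"))
        return(res("noncoding"))
    }
    # indel (minimal representation: one allele is length 1)
    span <- pos:(pos + nchar(ref) - 1L)
    actual <- refBaseAt(seqChar, pos, nchar(ref))
    if (actual != ref)
        stop("reference mismatch at ", chrom, ":", pos,
             ": variant ref '", ref, "' vs reference '", actual, "'")
    affected <- if (nchar(ref) > nchar(alt)) span[-1L] else c(pos, pos + 1L)
    offs <- vapply(affected, function(p) cdsOffset(tx, p), integer(1))
    inCds <- !is.na(offs)
    if (any(inCds)) {
        if (!all(inCds))
            warning("indel at ", chrom, ":", pos,
                    " spans a CDS boundary; classified as frameshift")
        lenDiff <- abs(nchar(ref) - nchar(alt))
        class <- if (!all(inCds) || lenDiff %% 3L != 0L) "frameshift"
                 else "inframe_indel"
        ci <- min(offs[inCds]) %/% 3L + 1L
        return(res(class, ci,
                   substitution = paste0(ci, if (class == "frameshift")
                       "fs" else "inframe")))
    }
    if (any(affected %in% splicePositions(tx, spliceWindow)))
        return(res("splice"))
    res("noncoding")
}

#' Annotate all panel variants with coding consequences
#'
#' Each variant is classified against the transcript whose CDS footprint
#' (extended by the splice window) contains it; variants outside every
#' transcript are \code{noncoding}.
#'
#' @param x a \linkS4class{CloneScreenPanel} or data.frame with chrom, pos,
#'   ref, alt.
#' @param transcripts named list of \linkS4class{TranscriptModel}
#'   (\code{\link{readGeneModels}}).
#' @param refSeqs reference sequences (\code{\link{readReference}}).
#' @param spliceWindow see \code{\link{classifyVariant}}.
#' @return \code{DataFrame} parallel to the variants: gene, txId,
#'   codonIndex, refAa, altAa, consequence, substitution.
#' @export
annotateVariants <- function(x, transcripts, refSeqs, spliceWindow = 2L) {
    if (is(x, "CloneScreenPanel")) {
        gr <- rowRanges(x)
        v <- data.frame(chrom = as.character(seqnames(gr)),
                        pos = start(gr), ref = mcols(gr)$ref,
                        alt = mcols(gr)$alt, stringsAsFactors = FALSE)
    } else v <- as.data.frame(x)
    seqChars <- if (is.character(refSeqs)) refSeqs else
        structure(as.character(refSeqs), names = names(refSeqs))
    ranges <- do.call(rbind, lapply(transcripts, function(tx) {
        data.frame(chrom = tx@chrom,
                   lo = min(BiocGenerics::start(tx@exons)) - spliceWindow,
                   hi = max(BiocGenerics::end(tx@exons)) + spliceWindow)
    }))
    rows <- lapply(seq_len(nrow(v)), function(i) {
        hit <- which(ranges$chrom == v$chrom[i] & v$pos[i] >= ranges$lo &
                     v$pos[i] <= ranges$hi)
        if (!length(hit))
            return(data.frame(gene = NA_character_, txId = NA_character_,
                              codonIndex = NA_integer_,
                              refAa = NA_character_, altAa = NA_character_,
                              consequence = "noncoding",
                              substitution = NA_character_,
                              stringsAsFactors = FALSE))
        classifyVariant(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                        transcripts[[hit[1L]]], seqChars, spliceWindow)
    })
    DataFrame(do.call(rbind, rows))
}

#' Is a consequence class coding?
#'
#' Non-coding variants are excluded from the somatic analysis; missense,
#' synonymous, nonsense, frameshift and in-frame indels count as coding, and
#' splice-site variants count per \code{countSpliceAsCoding} (default TRUE).
#'
#' @param consequence character vector of consequence classes.
#' @param config a \linkS4class{FilterConfig}.
#' @return logical vector.
#' @export
isCoding <- function(consequence, config = filterConfig()) {
    always <- c("missense", "synonymous", "nonsense", "frameshift",
                "inframe_indel")
    consequence %in% always |
        (consequence == "splice" & config@countSpliceAsCoding)
}
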