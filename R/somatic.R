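#' Apply site hard filters for one clone
#'
#' GATK-style removal semantics with strict inequalities: a record fails iff
#' \code{qd < qdMin} OR \code{fs > fsMax} OR \code{mq < mqMin} OR the
#' clone's \code{depth < dpMin} OR the clone's \code{gq < gqMin}. Boundary
#' values pass. Missing values fail their comparison when
#' \code{missingAnnotationFails} (default), else pass.
#'
#' @param panel a \linkS4class{CloneScreenPanel}.
#' @param clone clone sample name.
#' @param config a \linkS4class{FilterConfig}.
#' @return logical vector, TRUE where the record is retained.
#' @export
applyHardFilters <- function(panel, clone, config = filterConfig()) {
    if (!clone %in% colnames(panel))
        stop("unknown sample: ", clone)
    mc <- mcols(rowRanges(panel))
    dp <- assay(panel, "depth")[, clone]
    gq <- assay(panel, "gq")[, clone]
    cmp <- function(x, fails) {   # TRUE where the criterion REMOVES
        out <- fails(x)
        out[is.na(out)] <- config@missingAnnotationFails
        out
    }
    removed <- cmp(mc$qd, function(x) x < config@qdMin) |
        cmp(mc$fs, function(x) x > config@fsMax) |
        cmp(mc$mq, function(x) x < config@mqMin) |
        cmp(dp, function(x) x < config@dpMin) |
        cmp(gq, function(x) x < config@gqMin)
    !removed
}

#' Derive a clone's acquired somatic mutation set
#'
#' A variant is an acquired somatic mutation of a resistant clone iff it
#' passes the site hard filters and: clone VAF > \code{vafCloneMin};
#' parental VAF < \code{vafParentalMax}; every counter-screen sample VAF <
#' \code{vafCounterMax}; and the coding consequence is coding
#' (\code{\link{isCoding}}). A parental site with indeterminate VAF (zero
#' allele-depth denominator) but depth at least \code{parentalMinDepth}
#' counts as VAF 0; with less parental depth the site is uncallable and the
#' variant is excluded (recorded in provenance). Counter-screen samples with
#' indeterminate VAF count as 0 (no alt evidence).
#'
#' @param panel a \linkS4class{CloneScreenPanel}.
#' @param clone clone sample name (must differ from the parental sample).
#' @param consequences \code{DataFrame} from \code{\link{annotateVariants}},
#'   parallel to the panel rows.
#' @param config a \linkS4class{FilterConfig}.
#' @return A \linkS4class{SomaticSet}.
#' @export
acquiredSomaticSet <- function(panel, clone, consequences,
                               config = filterConfig()) {
    if (identical(clone, parentalName(panel)))
        stop("configuration error: clone must differ from the parental sample")
    if (!clone %in% colnames(panel))
        stop("unknown sample: ", clone)
    if (nrow(consequences) != nrow(panel))
        stop("consequences must be parallel to panel records")
    hard <- applyHardFilters(panel, clone, config)
    v <- vaf(panel)
    par <- parentalName(panel)
    parDepth <- assay(panel, "depth")[, par]
    parVaf <- v[, par]
    parCallable <- !is.na(parVaf) |
        (!is.na(parDepth) & parDepth >= config@parentalMinDepth)
    parVafEff <- ifelse(is.na(parVaf), 0, parVaf)
    cloneVaf <- v[, clone]
    cloneOk <- !is.na(cloneVaf) & cloneVaf > config@vafCloneMin
    ctr <- counterNames(panel)
    if (length(ctr)) {
        cv <- v[, ctr, drop = FALSE]
        cv[is.na(cv)] <- 0
        counterOk <- apply(cv < config@vafCounterMax, 1L, all)
        maxCounter <- apply(cv, 1L, max)
    } else {
        counterOk <- rep(TRUE, nrow(panel))
        maxCounter <- rep(NA_real_, nrow(panel))
    }
    coding <- isCoding(consequences$consequence, config)
    keep <- hard & cloneOk & parCallable &
        (parVafEff < config@vafParentalMax) & counterOk & coding
    uncallable <- hard & cloneOk & !parCallable
    gr <- rowRanges(panel)
    df <- DataFrame(chrom = as.character(seqnames(gr)), pos = start(gr),
                    ref = mcols(gr)$ref, alt = mcols(gr)$alt,
                    gene = consequences$gene,
                    codonIndex = consequences$codonIndex,
                    refAa = consequences$refAa, altAa = consequences$altAa,
                    consequence = consequences$consequence,
                    substitution = consequences$substitution,
                    cloneVaf = cloneVaf, parentalVaf = parVafEff,
                    maxCounterVaf = maxCounter)
    variants <- unique(df[keep, ])
    unc <- df[uncallable, c("chrom", "pos", "ref", "alt")]
    new("SomaticSet", clone = clone, variants = variants,
        provenance = list(
            config = config,
            criteria = c("hard_filters", "clone_vaf", "parental_vaf",
                         "counter_vaf", "coding"),
            nInput = nrow(panel), nPassedHardFilters = sum(hard),
            uncallable = unc))
}

#' @rdname SomaticSet-class
#' @param x a \code{SomaticSet}.
#' @export
somaticVariants <- function(x) x@variants

#' @rdname SomaticSet-class
#' @export
somaticKeys <- function(x) variantKeys(x@variants)

#' @rdname SomaticSet-class
#' @export
cloneName <- function(x) x@clone

setMethod("show", "SomaticSet", function(object) {
    cat("SomaticSet for clone", object@clone, "with",
        nrow(object@variants), "acquired somatic variant(s)\n")
    nu <- nrow(object@provenance$uncallable)
    if (!is.null(nu) && nu > 0)
        cat("  ", nu, "site(s) uncallable (insufficient parental depth)\n")
})

#' Write a per-clone somatic mutation TSV
#'
#' Columns: chrom, pos, ref, alt, gene, codon, aa_change, clone_vaf,
#' parental_vaf, max_counter_vaf, filters_evaluated.
#'
#' @param set a \linkS4class{SomaticSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSomaticTsv <- function(set, path) {
    v <- as.data.frame(set@variants)
    filt <- if (nrow(v)) paste(set@provenance$criteria, collapse = ",")
            else character()
    out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                      alt = v$alt, gene = v$gene, codon = v$codonIndex,
                      aa_change = v$substitution,
                      clone_vaf = round(v$cloneVaf, 4),
                      parental_vaf = round(v$parentalVaf, 4),
                      max_counter_vaf = round(v$maxCounterVaf, 4),
                      filters_evaluated = filt)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
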