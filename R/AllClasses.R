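#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start width mcols mcols<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

VALID_CONSEQUENCES <- c("missense", "synonymous", "nonsense", "frameshift",
                        "inframe_indel", "splice", "noncoding")

#' Multi-sample variant panel for a resistance screen
#'
#' A \code{CloneScreenPanel} holds the variant calls of one forward-genetics
#' screen: a parental cell line, the compound-resistant clones selected from
#' it, and an optional counter-screen panel (clones resistant to an unrelated
#' compound, used to subtract selection-independent background). It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are biallelic variant
#' records (multi-allelic sites are split on read-in), columns are samples.
#'
#' Row ranges carry the variant key (\code{ref}, \code{alt} in
#' \code{mcols()}) and the site-level calling annotations \code{qd}
#' (quality by depth), \code{fs} (Phred-scaled strand bias) and \code{mq}
#' (RMS mapping quality); missing annotations are \code{NA}, never 0.
#' Assays are \code{refDepth}, \code{altDepth}, \code{depth}, \code{gq}
#' (all integer) and \code{called} (logical: genotype present in the VCF).
#' \code{colData()$role} assigns each sample to \code{"parental"},
#' \code{"clone"} or \code{"counter"}.
#'
#' @seealso \code{\link{readScreenVcf}}, \code{\link{vaf}},
#'   \code{\link{acquiredSomaticSet}}
#' @export
setClass("CloneScreenPanel", contains = "RangedSummarizedExperiment")

PANEL_ASSAYS <- c("refDepth", "altDepth", "depth", "gq", "called")

setValidity("CloneScreenPanel", function(object) {
    msg <- character()
    if (!all(PANEL_ASSAYS %in% names(assays(object))))
        msg <- c(msg, paste0("assays must include: ",
                             paste(PANEL_ASSAYS, collapse = ", ")))
    cd <- colData(object)
    if (!"role" %in% names(cd)) {
        msg <- c(msg, "colData must have a 'role' column")
    } else {
        role <- cd$role
        if (!all(role %in% c("parental", "clone", "counter")))
            msg <- c(msg, "roles must be 'parental', 'clone' or 'counter'")
        if (sum(role == "parental") != 1L)
            msg <- c(msg, "exactly one parental sample required")
        if (sum(role == "clone") < 1L)
            msg <- c(msg, "at least one clone sample required")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "sample names must be unique")
    }
    mc <- mcols(rowRanges(object))
    need <- c("ref", "alt", "qd", "fs", "mq")
    if (!all(need %in% names(mc)))
        msg <- c(msg, paste0("row metadata must include: ",
                             paste(need, collapse = ", ")))
    else {
        bad <- !grepl("^[ACGT]+$", mc$ref) | !grepl("^[ACGT]+$", mc$alt) |
            mc$ref == mc$alt
        if (any(bad))
            msg <- c(msg, "ref/alt must be non-empty A/C/G/T strings and differ")
    }
    if (length(msg)) msg else TRUE
})

#' Hard-filter and somatic-call configuration
#'
#' Thresholds applied when deriving per-clone acquired somatic mutation sets.
#' Site hard filters follow GATK removal semantics with strict inequalities:
#' a record is removed iff \code{qd < qdMin} or \code{fs > fsMax} or
#' \code{mq < mqMin} or clone \code{depth < dpMin} or clone \code{gq < gqMin};
#' boundary values pass. The somatic criteria require clone VAF strictly above
#' \code{vafCloneMin}, parental VAF strictly below \code{vafParentalMax}, and
#' every counter-screen sample VAF strictly below \code{vafCounterMax}.
#'
#' @slot qdMin minimum quality-by-depth (default 2).
#' @slot fsMax maximum Phred-scaled strand bias (default 60).
#' @slot mqMin minimum RMS mapping quality (default 40).
#' @slot dpMin minimum clone read depth (default 3).
#' @slot gqMin minimum clone genotype quality (default 7).
#' @slot vafCloneMin clone VAF must exceed this (default 0.2).
#' @slot vafParentalMax parental VAF must be below this (default 0.01).
#' @slot vafCounterMax each counter-screen VAF must be below this (default 0.05).
#' @slot parentalMinDepth reads required before an indeterminate parental VAF
#'   counts as 0; below it the variant is uncallable and excluded (default 10).
#' @slot countSpliceAsCoding treat splice-site variants as coding (default TRUE).
#' @slot missingAnnotationFails a missing QD/FS/MQ/DP/GQ value fails its
#'   filter (default TRUE, conservative).
#' @seealso \code{\link{filterConfig}}
#' @export
setClass("FilterConfig", representation(
    qdMin = "numeric", fsMax = "numeric", mqMin = "numeric",
    dpMin = "numeric", gqMin = "numeric",
    vafCloneMin = "numeric", vafParentalMax = "numeric",
    vafCounterMax = "numeric", parentalMinDepth = "numeric",
    countSpliceAsCoding = "logical", missingAnnotationFails = "logical"))

setValidity("FilterConfig", function(object) {
    msg <- character()
    v <- c(object@vafCloneMin, object@vafParentalMax, object@vafCounterMax)
    if (any(v < 0 | v > 1))
        msg <- c(msg, "VAF thresholds must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Per-clone acquired somatic mutation set
#'
#' The coding variants a resistant clone acquired relative to its parental
#' line: clone VAF above threshold, parental (and counter-screen) VAF below
#' threshold, site hard filters passed. Produced by
#' \code{\link{acquiredSomaticSet}}.
#'
#' @slot clone sample name.
#' @slot variants \code{DataFrame} with one row per somatic variant: chrom,
#'   pos, ref, alt, gene, codonIndex, refAa, altAa, consequence, cloneVaf,
#'   parentalVaf, maxCounterVaf.
#' @slot provenance list recording the \code{FilterConfig} used, the criteria
#'   evaluated, and uncallable sites (parental depth below the guard).
#' @export
setClass("SomaticSet", representation(
    clone = "character", variants = "DataFrame", provenance = "list"))

#' Clone relatedness by shared somatic mutations
#'
#' Pairwise counts of shared somatic variants between clones, with clones
#' grouped (connected components) when a pair shares at least
#' \code{threshold} mutations. Related groups indicate common descent of
#' clones before compound selection.
#'
#' @slot samples clone names, in matrix order.
#' @slot sharedCounts symmetric matrix; diagonal is each clone's somatic set
#'   size.
#' @slot threshold sharing threshold used for grouping.
#' @slot groups list of character vectors partitioning the clones.
#' @export
setClass("RelatednessMatrix", representation(
    samples = "character", sharedCounts = "matrix",
    threshold = "numeric", groups = "list"))

setValidity("RelatednessMatrix", function(object) {
    m <- object@sharedCounts
    msg <- character()
    if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "sharedCounts must be symmetric")
    if (!setequal(unlist(object@groups), object@samples) ||
        length(unlist(object@groups)) != length(object@samples))
        msg <- c(msg, "groups must partition samples")
    if (length(msg)) msg else TRUE
})

#' Gene- and codon-level mutation recurrence report
#'
#' Candidate-target ranking of a screen: for each gene, how many clones carry
#' at least one qualifying somatic variant (raw), how many after collapsing
#' related clone groups to one voter (collapsed), plus codon-level recurrence
#' (the same codon hit in independent clones, possibly with different amino
#' acid substitutions -- strong evidence of positive selection).
#'
#' @slot geneTable \code{DataFrame}: gene, rawCount, collapsedCount,
#'   supportingClones, consequenceClasses, nRecurrentCodons.
#' @slot codonTable \code{DataFrame}: gene, codonIndex, substitutions,
#'   supportingClones, nUnrelatedClones, recurrent.
#' @slot ranking genes ordered by collapsed count, then recurrent codons,
#'   then name.
#' @slot relatedness the \linkS4class{RelatednessMatrix} used for collapsing.
#' @export
setClass("RecurrenceReport", representation(
    geneTable = "DataFrame", codonTable = "DataFrame",
    ranking = "character", relatedness = "RelatednessMatrix"))

#' Normalized log-logistic dose-response fit
#'
#' Parameters of the "log(inhibitor) vs normalized response" model
#' \deqn{y = 100 / (1 + 10^{(x - \log_{10} IC_{50})\,h})}
#' with \eqn{x = \log_{10}} concentration, top fixed at 100 and bottom at 0
#' (a 4-parameter variant with free top/bottom is available). Standard errors
#' come from the curvature of the least-squares objective.
#'
#' @slot compound compound name.
#' @slot sample cell-line name.
#' @slot logIc50 log10 molar IC50.
#' @slot hill Hill slope.
#' @slot top,bottom response asymptotes (percent).
#' @slot seLogIc50,seHill standard errors.
#' @slot converged FALSE when the optimizer failed or the curve is
#'   non-responsive; never an exception.
#' @slot n number of observations fitted.
#' @seealso \code{\link{fitDoseResponse}}, \code{\link{foldResistance}}
#' @export
setClass("DoseResponseFit", representation(
    compound = "character", sample = "character",
    logIc50 = "numeric", hill = "numeric",
    top = "numeric", bottom = "numeric",
    seLogIc50 = "numeric", seHill = "numeric",
    converged = "logical", n = "integer"))
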