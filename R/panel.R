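#' Construct a CloneScreenPanel
#'
#' Usually made by \code{\link{readScreenVcf}}; this constructor is exposed
#' for programmatic panels (tests, simulations).
#'
#' @param variants data.frame or DataFrame with columns \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt} and optionally \code{qd},
#'   \code{fs}, \code{mq} (missing columns become \code{NA}).
#' @param refDepth,altDepth,depth,gq integer matrices, variants x samples,
#'   with sample names as column names.
#' @param called logical matrix; defaults to \code{depth > 0} with \code{NA}
#'   treated as uncalled.
#' @param parental single parental sample name.
#' @param clones character vector of resistant-clone sample names.
#' @param counterScreen character vector of counter-screen sample names.
#' @return A \linkS4class{CloneScreenPanel}.
#' @examples
#' v <- data.frame(chrom = "chr1", pos = c(11, 25), ref = "G", alt = "A")
#' m <- function(x) matrix(x, 2, 2, dimnames = list(NULL, c("par", "clA")))
#' p <- CloneScreenPanel(v, refDepth = m(50L), altDepth = m(c(0L, 0L, 30L, 40L)),
#'                       depth = m(90L), gq = m(99L),
#'                       parental = "par", clones = "clA")
#' vaf(p)
#' @export
CloneScreenPanel <- function(variants, refDepth, altDepth, depth, gq,
                             called = NULL, parental, clones,
                             counterScreen = character()) {
    variants <- as.data.frame(variants)
    for (col in c("qd", "fs", "mq"))
        if (is.null(variants[[col]])) variants[[col]] <- NA_real_
    samples <- c(parental, clones, counterScreen)
    if (anyDuplicated(samples))
        stop("sample names must be unique across roles")
    role <- c("parental", rep("clone", length(clones)),
              rep("counter", length(counterScreen)))
    asMat <- function(m, mode) {
        m <- as.matrix(m)
        storage.mode(m) <- mode
        if (is.null(colnames(m)))
            stop("assay matrices need sample column names")
        m[, samples, drop = FALSE]
    }
    refDepth <- asMat(refDepth, "integer")
    altDepth <- asMat(altDepth, "integer")
    depth <- asMat(depth, "integer")
    gq <- asMat(gq, "integer")
    if (is.null(called)) {
        called <- !is.na(depth) & depth > 0L
    } else {
        called <- asMat(called, "logical")
        called[is.na(called)] <- FALSE
    }
    gr <- GRanges(variants$chrom,
                  IRanges(variants$pos, width = nchar(variants$ref)))
    mcols(gr) <- DataFrame(ref = toupper(variants$ref),
                           alt = toupper(variants$alt),
                           qd = as.numeric(variants$qd),
                           fs = as.numeric(variants$fs),
                           mq = as.numeric(variants$mq))
    se <- SummarizedExperiment(
        assays = SimpleList(refDepth = refDepth, altDepth = altDepth,
                            depth = depth, gq = gq, called = called),
        rowRanges = gr,
        colData = DataFrame(role = role, row.names = samples))
    new("CloneScreenPanel", se)
}

#' @rdname CloneScreenPanel
#' @param x,object a \code{CloneScreenPanel}.
#' @export
parentalName <- function(x) colnames(x)[colData(x)$role == "parental"]

#' @rdname CloneScreenPanel
#' @export
cloneNames <- function(x) colnames(x)[colData(x)$role == "clone"]

#' @rdname CloneScreenPanel
#' @export
counterNames <- function(x) colnames(x)[colData(x)$role == "counter"]

#' Variant identity keys
#'
#' \code{"chrom:pos:ref:alt"} strings; two variants are the same iff all four
#' fields are equal. This is the identity under which somatic sets are
#' intersected when counting mutations shared between clones.
#'
#' @param x a \code{CloneScreenPanel} or the \code{variants} DataFrame of a
#'   \linkS4class{SomaticSet}.
#' @return character vector.
#' @export
variantKeys <- function(x) {
    if (is(x, "CloneScreenPanel")) {
        gr <- rowRanges(x)
        paste(as.character(seqnames(gr)), start(gr),
              mcols(gr)$ref, mcols(gr)$alt, sep = ":")
    } else {
        paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
    }
}

#' Variant allele frequency
#'
#' \code{computeVaf} is the scalar/vector rule: alt reads over informative
#' reads, \code{altDepth / (refDepth + altDepth)}. The denominator uses
#' allele depths rather than DP because DP may count uninformative reads;
#' this keeps VAF in [0, 1]. A zero denominator gives \code{NA}
#' (indeterminate -- a value, not an error). The \code{vaf} method returns
#' the variants x samples VAF matrix of a panel, with uncalled entries
#' \code{NA}.
#'
#' @param refDepth,altDepth non-negative read counts (vectorized).
#' @return numeric in [0, 1] or NA.
#' @examples
#' computeVaf(60, 40)   # 0.4
#' computeVaf(0, 0)     # NA
#' @export
computeVaf <- function(refDepth, altDepth) {
    denom <- refDepth + altDepth
    ifelse(!is.na(denom) & denom > 0, altDepth / denom, NA_real_)
}

#' @rdname computeVaf
#' @param x a \code{CloneScreenPanel}.
#' @export
setGeneric("vaf", function(x) standardGeneric("vaf"))

#' @rdname computeVaf
#' @export
setMethod("vaf", "CloneScreenPanel", function(x) {
    v <- computeVaf(assay(x, "refDepth"), assay(x, "altDepth"))
    v[!assay(x, "called")] <- NA_real_
    v
})

setMethod("show", "CloneScreenPanel", function(object) {
    cat("CloneScreenPanel with", nrow(object), "variant records\n")
    cat("  parental:", parentalName(object), "\n")
    cat("  clones (", length(cloneNames(object)), "): ",
        paste(cloneNames(object), collapse = ", "), "\n", sep = "")
    if (length(counterNames(object)))
        cat("  counter-screen (", length(counterNames(object)), "): ",
            paste(counterNames(object), collapse = ", "), "\n", sep = "")
})

#' Create a filter configuration
#'
#' Defaults are the screen's published criteria: sites removed when
#' QD < 2, FS > 60, MQ < 40, clone DP < 3 or clone GQ < 7 (strict
#' inequalities, boundary values pass); acquired somatic calls require clone
#' VAF > 0.2, parental VAF < 0.01 and each counter-screen VAF < 0.05.
#'
#' @param qdMin,fsMax,mqMin,dpMin,gqMin site/genotype hard-filter thresholds.
#' @param vafCloneMin,vafParentalMax,vafCounterMax somatic VAF criteria.
#' @param parentalMinDepth callability guard for the parental sample.
#' @param countSpliceAsCoding,missingAnnotationFails behaviour toggles; see
#'   \linkS4class{FilterConfig}.
#' @return A \linkS4class{FilterConfig}.
#' @examples
#' filterConfig()
#' filterConfig(vafCloneMin = 0.3)
#' @export
filterConfig <- function(qdMin = 2, fsMax = 60, mqMin = 40, dpMin = 3,
                         gqMin = 7, vafCloneMin = 0.2, vafParentalMax = 0.01,
                         vafCounterMax = 0.05, parentalMinDepth = 10,
                         countSpliceAsCoding = TRUE,
                         missingAnnotationFails = TRUE) {
    if (!(vafParentalMax <= vafCounterMax && vafCounterMax <= vafCloneMin))
        warning("unusual VAF threshold ordering: expected ",
                "vafParentalMax <= vafCounterMax <= vafCloneMin")
    new("FilterConfig", qdMin = qdMin, fsMax = fsMax, mqMin = mqMin,
        dpMin = dpMin, gqMin = gqMin, vafCloneMin = vafCloneMin,
        vafParentalMax = vafParentalMax, vafCounterMax = vafCounterMax,
        parentalMinDepth = parentalMinDepth,
        countSpliceAsCoding = countSpliceAsCoding,
        missingAnnotationFails = missingAnnotationFails)
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig\n")
    cat(sprintf("  hard filters: QD < %g, FS > %g, MQ < %g, DP < %g, GQ < %g removed\n",
                object@qdMin, object@fsMax, object@mqMin, object@dpMin,
                object@gqMin))
    cat(sprintf("  somatic: clone VAF > %g, parental VAF < %g, counter VAF < %g\n",
                object@vafCloneMin, object@vafParentalMax,
                object@vafCounterMax))
    cat(sprintf("  parental callability: depth >= %g; splice coding: %s; missing fails: %s\n",
                object@parentalMinDepth, object@countSpliceAsCoding,
                object@missingAnnotationFails))
})
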