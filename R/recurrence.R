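#' Number of somatic mutations shared by two clones
#'
#' Cardinality of the intersection of two clones' somatic sets under exact
#' variant-key equality (chrom, pos, ref, alt). A high shared count indicates
#' the clones descend from a common ancestor that existed before compound
#' selection.
#'
#' @param a,b \linkS4class{SomaticSet}s from the same panel.
#' @return non-negative integer.
#' @export
sharedCount <- function(a, b) length(intersect(somaticKeys(a), somaticKeys(b)))

unionFind <- function(n, pairs) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
        if (ri != rj) parent[rj] <- ri
    }
    vapply(seq_len(n), find, integer(1))
}

#' Clone relatedness from shared somatic mutations
#'
#' Computes all pairwise shared counts and groups clones whose pairwise
#' sharing reaches \code{shareThreshold} (connected components, i.e. the
#' transitive closure of pairwise relatedness).
#'
#' @param sets list of \linkS4class{SomaticSet} (at least 2, unique clone
#'   names).
#' @param shareThreshold pairs sharing at least this many mutations are
#'   related (default 20; between a related pair's expected sharing and the
#'   coincidental overlap of independent hypermutated clones).
#' @return A \linkS4class{RelatednessMatrix}.
#' @export
relatedness <- function(sets, shareThreshold = 20) {
    clones <- vapply(sets, cloneName, character(1))
    if (anyDuplicated(clones))
        stop("configuration error: duplicate clone names")
    if (length(sets) < 2L)
        stop("need at least 2 clones")
    n <- length(sets)
    m <- matrix(0L, n, n, dimnames = list(clones, clones))
    for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- sharedCount(sets[[i]], sets[[j]])
    pairs <- which(m >= shareThreshold & upper.tri(m), arr.ind = TRUE)
    comp <- unionFind(n, pairs)
    groups <- unname(lapply(split(clones, comp), unname))
    new("RelatednessMatrix", samples = clones, sharedCounts = m,
        threshold = shareThreshold, groups = groups)
}

#' @rdname RelatednessMatrix-class
#' @param x a \code{RelatednessMatrix}.
#' @export
relatedGroups <- function(x) x@groups

#' @rdname RelatednessMatrix-class
#' @export
sharedCounts <- function(x) x@sharedCounts

setMethod("show", "RelatednessMatrix", function(object) {
    cat("RelatednessMatrix for", length(object@samples),
        "clones (threshold", object@threshold, ")\n")
    print(object@sharedCounts)
    multi <- Filter(function(g) length(g) > 1L, object@groups)
    if (length(multi))
        cat("related groups:",
            paste(vapply(multi, paste, character(1), collapse = "+"),
                  collapse = "; "), "\n")
    else cat("no related clones\n")
})

groupIndex <- function(rel) {
    idx <- integer(length(rel@samples))
    names(idx) <- rel@samples
    for (g in seq_along(rel@groups)) idx[rel@groups[[g]]] <- g
    idx
}

#' Gene- and codon-level recurrence across clones
#'
#' For each gene: the raw clone count (clones with at least one qualifying
#' somatic variant) and the collapsed count, in which each related clone
#' group votes once (a group votes if any member is mutated). For each
#' (gene, codon): the distinct amino-acid substitutions observed and the
#' supporting clones; a codon is recurrent when hit in at least two
#' unrelated clones (distinct groups). Genes are ranked by collapsed count,
#' then number of recurrent codons, then name (deterministic).
#'
#' @param sets list of \linkS4class{SomaticSet}.
#' @param rel a \linkS4class{RelatednessMatrix}; by default computed from
#'   \code{sets} at threshold 20.
#' @return A \linkS4class{RecurrenceReport}.
#' @export
geneRecurrence <- function(sets, rel = relatedness(sets)) {
    gidx <- groupIndex(rel)
    perClone <- lapply(sets, function(s) {
        v <- as.data.frame(s@variants)
        v <- v[!is.na(v$gene), , drop = FALSE]
        if (nrow(v)) v$clone <- cloneName(s)
        v
    })
    all <- do.call(rbind, perClone[vapply(perClone, nrow, integer(1)) > 0])
    if (is.null(all) || nrow(all) == 0L) {
        empty <- DataFrame(gene = character(), rawCount = integer(),
                           collapsedCount = integer(),
                           supportingClones = character(),
                           consequenceClasses = character(),
                           nRecurrentCodons = integer())
        emptyCodon <- DataFrame(gene = character(), codonIndex = integer(),
                                substitutions = character(),
                                supportingClones = character(),
                                nUnrelatedClones = integer(),
                                recurrent = logical())
        return(new("RecurrenceReport", geneTable = empty,
                   codonTable = emptyCodon, ranking = character(),
                   relatedness = rel))
    }
    cod <- all[!is.na(all$codonIndex), , drop = FALSE]
    codonRows <- do.call(rbind, lapply(
        split(cod, paste(cod$gene, cod$codonIndex, sep = "@")),
        function(d) {
            clones <- sort(unique(d$clone))
            subs <- sort(unique(ifelse(is.na(d$altAa), "indel", d$altAa)))
            nUnrel <- length(unique(gidx[clones]))
            data.frame(gene = d$gene[1L], codonIndex = d$codonIndex[1L],
                       substitutions = paste(subs, collapse = "/"),
                       supportingClones = paste(clones, collapse = ","),
                       nUnrelatedClones = nUnrel,
                       recurrent = nUnrel >= 2L, stringsAsFactors = FALSE)
        }))
    if (is.null(codonRows))
        codonRows <- data.frame(gene = character(), codonIndex = integer(),
                                substitutions = character(),
                                supportingClones = character(),
                                nUnrelatedClones = integer(),
                                recurrent = logical())
    codonRows <- codonRows[order(codonRows$gene, codonRows$codonIndex), ,
                           drop = FALSE]
    geneRows <- do.call(rbind, lapply(split(all, all$gene), function(d) {
        clones <- sort(unique(d$clone))
        rc <- sum(codonRows$recurrent[codonRows$gene == d$gene[1L]])
        data.frame(gene = d$gene[1L], rawCount = length(clones),
                   collapsedCount = length(unique(gidx[clones])),
                   supportingClones = paste(clones, collapse = ","),
                   consequenceClasses = paste(sort(unique(d$consequence)),
                                              collapse = ","),
                   nRecurrentCodons = rc, stringsAsFactors = FALSE)
    }))
    ord <- order(-geneRows$collapsedCount, -geneRows$nRecurrentCodons,
                 geneRows$gene)
    geneRows <- geneRows[ord, , drop = FALSE]
    rownames(geneRows) <- NULL
    rownames(codonRows) <- NULL
    new("RecurrenceReport", geneTable = DataFrame(geneRows),
        codonTable = DataFrame(codonRows), ranking = geneRows$gene,
        relatedness = rel)
}

#' @rdname RecurrenceReport-class
#' @param x a \code{RecurrenceReport}.
#' @export
geneTable <- function(x) x@geneTable

#' @rdname RecurrenceReport-class
#' @export
codonTable <- function(x) x@codonTable

#' Candidate target genes above a recurrence cutoff
#'
#' Genes whose collapsed clone count reaches \code{minClones}, in ranking
#' order (collapsed count desc, recurrent codons desc, gene name).
#'
#' @param report a \linkS4class{RecurrenceReport}.
#' @param minClones minimum collapsed clone count.
#' @return character vector of gene symbols.
#' @export
rankCandidates <- function(report, minClones = 2L) {
    gt <- report@geneTable
    gt$gene[gt$collapsedCount >= minClones]
}

setMethod("show", "RecurrenceReport", function(object) {
    cat("RecurrenceReport:", nrow(object@geneTable), "gene(s),",
        sum(object@codonTable$recurrent), "recurrent codon(s)\n")
    top <- utils::head(as.data.frame(object@geneTable), 5L)
    if (nrow(top)) print(top)
})

#' Write recurrence report tables
#'
#' Writes the gene table, codon table and relatedness matrix as TSV plus a
#' JSON file with full provenance.
#'
#' @param report a \linkS4class{RecurrenceReport}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named vector of the paths written, invisibly.
#' @export
writeRecurrenceReport <- function(report, dir, prefix = "recurrence") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pGene <- file.path(dir, paste0(prefix, "_genes.tsv"))
    pCodon <- file.path(dir, paste0(prefix, "_codons.tsv"))
    pRel <- file.path(dir, paste0(prefix, "_relatedness.tsv"))
    pJson <- file.path(dir, paste0(prefix, ".json"))
    utils::write.table(as.data.frame(report@geneTable), pGene, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report@codonTable), pCodon, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report@relatedness@sharedCounts, pRel, sep = "\t",
                       quote = FALSE, col.names = NA)
    jsonlite::write_json(list(
        ranking = report@ranking,
        shareThreshold = report@relatedness@threshold,
        relatedGroups = report@relatedness@groups,
        genes = as.data.frame(report@geneTable),
        codons = as.data.frame(report@codonTable)),
        pJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(genes = pGene, codons = pCodon, relatedness = pRel,
                json = pJson))
}
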