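#' Run the full screen analysis
#'
#' End-to-end: read the multi-sample VCF, reference and gene models;
#' annotate variants to coding consequences; derive each clone's acquired
#' somatic mutation set; compute clone relatedness; rank candidate genes by
#' recurrence. When \code{outDir} is given, writes per-clone somatic TSVs,
#' the relatedness matrix, the gene/codon recurrence tables (TSV + JSON) and
#' a run log recording every threshold that affected the output. The run is
#' deterministic given its inputs.
#'
#' @param vcf multi-sample VCF path.
#' @param fasta reference FASTA path.
#' @param geneModels gene-model TSV path.
#' @param parental,clones,counterScreen sample role assignment.
#' @param config a \linkS4class{FilterConfig}.
#' @param shareThreshold relatedness grouping threshold (shared mutations).
#' @param minClones recurrence cutoff for \code{\link{rankCandidates}}.
#' @param outDir optional output directory.
#' @return list: \code{panel}, \code{somaticSets}, \code{relatedness},
#'   \code{report} (\linkS4class{RecurrenceReport}), \code{candidates},
#'   \code{paths} (when \code{outDir} given).
#' @export
runScreen <- function(vcf, fasta, geneModels, parental, clones,
                      counterScreen = character(),
                      config = filterConfig(), shareThreshold = 20,
                      minClones = 2L, outDir = NULL) {
    for (p in c(vcf, fasta, geneModels))
        if (!file.exists(p))
            stop("config error: input file not found: ", p)
    panel <- readScreenVcf(vcf, parental, clones, counterScreen)
    refSeqs <- readReference(fasta)
    chroms <- unique(as.character(seqnames(rowRanges(panel))))
    absent <- setdiff(chroms, names(refSeqs))
    if (length(absent))
        stop("variant chrom(s) absent from reference: ",
             paste(absent, collapse = ", "))
    transcripts <- readGeneModels(geneModels)
    consequences <- annotateVariants(panel, transcripts, refSeqs)
    somaticSets <- lapply(clones, function(cl)
        acquiredSomaticSet(panel, cl, consequences, config))
    names(somaticSets) <- clones
    rel <- if (length(clones) >= 2L)
        relatedness(somaticSets, shareThreshold)
    else {
        m <- matrix(nrow(somaticSets[[1L]]@variants), 1L, 1L,
                    dimnames = list(clones, clones))
        new("RelatednessMatrix", samples = clones, sharedCounts = m,
            threshold = shareThreshold, groups = list(clones))
    }
    report <- geneRecurrence(somaticSets, rel)
    candidates <- rankCandidates(report, minClones)
    paths <- NULL
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        somaticPaths <- vapply(clones, function(cl) {
            p <- file.path(outDir, paste0("somatic_", cl, ".tsv"))
            writeSomaticTsv(somaticSets[[cl]], p)
            p
        }, character(1))
        reportPaths <- writeRecurrenceReport(report, outDir)
        logPath <- file.path(outDir, "run_log.txt")
        writeLines(c(
            paste0("ForwardScreen runScreen ", utils::packageVersion("ForwardScreen")),
            paste0("vcf: ", vcf), paste0("fasta: ", fasta),
            paste0("gene_models: ", geneModels),
            paste0("parental: ", parental),
            paste0("clones: ", paste(clones, collapse = ",")),
            paste0("counter_screen: ", paste(counterScreen, collapse = ",")),
            sprintf("hard_filters: qd_min=%g fs_max=%g mq_min=%g dp_min=%g gq_min=%g",
                    config@qdMin, config@fsMax, config@mqMin, config@dpMin,
                    config@gqMin),
            sprintf("somatic: vaf_clone_min=%g vaf_parental_max=%g vaf_counter_max=%g parental_min_depth=%g",
                    config@vafCloneMin, config@vafParentalMax,
                    config@vafCounterMax, config@parentalMinDepth),
            sprintf("annotation: count_splice_as_coding=%s missing_annotation_fails=%s",
                    config@countSpliceAsCoding,
                    config@missingAnnotationFails),
            sprintf("recurrence: share_threshold=%g min_clones=%d",
                    shareThreshold, as.integer(minClones)),
            paste0("top_candidates: ", paste(candidates, collapse = ","))),
            logPath)
        paths <- c(somatic = list(somaticPaths), as.list(reportPaths),
                   log = logPath)
    }
    list(panel = panel, somaticSets = somaticSets, relatedness = rel,
         report = report, candidates = candidates, paths = paths)
}

#' Fit all dose-response curves in a viability table
#'
#' Normalizes each (compound, sample) curve to its vehicle wells, fits the
#' normalized log-logistic model, and reports fold-resistance of every
#' sample versus the designated parental sample for the same compound.
#' Non-converging curves are flagged and the run continues.
#'
#' @param viability data.frame (see \code{\link{readViabilityTable}}) or a
#'   path to one.
#' @param parentalSample reference sample for fold-resistance.
#' @param fixedAsymptotes see \code{\link{fitDoseResponse}}.
#' @param outDir optional output directory for a TSV of the fit table.
#' @return data.frame: compound, sample, ic50_molar, log_ic50, hill,
#'   se_log_ic50, se_hill, converged, fold_vs_parental.
#' @export
runDose <- function(viability, parentalSample, fixedAsymptotes = TRUE,
                    outDir = NULL) {
    if (is.character(viability))
        viability <- readViabilityTable(viability)
    if (!parentalSample %in% viability$sample)
        stop("config error: unknown parental sample: ", parentalSample)
    norm <- normalizeToVehicle(viability)
    curves <- split(norm, paste(norm$compound, norm$sample, sep = "\r"))
    fits <- lapply(curves, function(d) {
        dd <- d[!d$is_vehicle, ]
        fitDoseResponse(dd$concentration_molar, dd$reading,
                        compound = d$compound[1L], sample = d$sample[1L],
                        fixedAsymptotes = fixedAsymptotes)
    })
    tab <- do.call(rbind, lapply(fits, function(f) data.frame(
        compound = f@compound, sample = f@sample,
        ic50_molar = if (f@converged) 10^f@logIc50 else NA_real_,
        log_ic50 = f@logIc50, hill = f@hill,
        se_log_ic50 = f@seLogIc50, se_hill = f@seHill,
        converged = f@converged, stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
    tab$fold_vs_parental <- NA_real_
    for (i in seq_len(nrow(tab))) {
        j <- which(tab$compound == tab$compound[i] &
                   tab$sample == parentalSample)
        if (length(j) == 1L && tab$converged[i] && tab$converged[j])
            tab$fold_vs_parental[i] <- tab$ic50_molar[i] / tab$ic50_molar[j]
    }
    tab <- tab[order(tab$compound, tab$sample), , drop = FALSE]
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(tab, file.path(outDir, "dose_response_fits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tab
}
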