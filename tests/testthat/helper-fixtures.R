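# Shared fixture builders: tiny VCFs, toy transcripts with embedded CDS,
# programmatic panels, and the brute-force translation oracle used to
# cross-check codon annotation.

vcfHeaderLines <- function(samples) {
    c("##fileformat=VCFv4.2",
      "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
      "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      "##contig=<ID=chr1>",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
}

writeTestVcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
    writeLines(c(vcfHeaderLines(samples), records), path)
    path
}

# panel with explicit per-sample allele depths; sites get passing
# annotations unless overridden
makeTestPanel <- function(altDepth, refDepth, parental, clones,
                          counterScreen = character(),
                          qd = 25, fs = 1, mq = 60, depth = NULL,
                          gq = 90, consequence = "missense") {
    n <- nrow(altDepth)
    if (is.null(depth)) depth <- refDepth + altDepth
    gqm <- matrix(gq, n, ncol(altDepth), dimnames = dimnames(altDepth))
    variants <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                           ref = "G", alt = "A",
                           qd = rep_len(qd, n), fs = rep_len(fs, n),
                           mq = rep_len(mq, n))
    panel <- CloneScreenPanel(variants, refDepth = refDepth,
                              altDepth = altDepth, depth = depth, gq = gqm,
                              parental = parental, clones = clones,
                              counterScreen = counterScreen)
    attr(panel, "testConsequences") <- S4Vectors::DataFrame(
        gene = rep("GENEX", n), txId = rep("TX", n),
        codonIndex = seq_len(n), refAa = rep("G", n),
        altAa = rep("S", n),
        consequence = rep_len(consequence, n),
        substitution = paste0("G", seq_len(n), "S"))
    panel
}

constantConsequences <- function(panel, consequence = "missense") {
    n <- nrow(panel)
    S4Vectors::DataFrame(
        gene = rep("GENEX", n), txId = rep("TX", n),
        codonIndex = seq_len(n), refAa = rep("G", n), altAa = rep("S", n),
        consequence = rep_len(consequence, n),
        substitution = paste0("G", seq_len(n), "S"))
}

# embed a CDS into a random chromosome; returns transcript + sequences
makeToyTx <- function(cds, strand = "+", exonLens = NULL, intronLen = 20L,
                      pad = 50L, gene = "GENEX", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nchar(cds) %% 3 == 0)
    if (is.null(exonLens)) exonLens <- nchar(cds)
    stopifnot(sum(exonLens) == nchar(cds))
    nEx <- length(exonLens)
    L <- 2L * pad + nchar(cds) + (nEx - 1L) * intronLen
    seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    starts <- integer(nEx); ends <- integer(nEx)
    p <- pad + 1L
    for (k in seq_len(nEx)) {
        starts[k] <- p
        ends[k] <- p + exonLens[k] - 1L
        p <- ends[k] + intronLen + 1L
    }
    tx <- TranscriptModel(gene, paste0("TX_", gene), "chrT", strand,
                          starts, ends)
    cdsChars <- strsplit(cds, "")[[1]]
    gpos <- vapply(seq_len(nchar(cds)) - 1L,
                   function(o) cdsToGenomic(tx, o), integer(1))
    seq[gpos] <- if (strand == "-") chartr("ACGT", "TGCA", cdsChars)
                 else cdsChars
    list(tx = tx, seqs = c(chrT = paste(seq, collapse = "")))
}

randomCds <- function(nCodons) {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    paste(c("ATG", sample(setdiff(sense, "ATG"), nCodons - 2L,
                          replace = TRUE), "TAA"), collapse = "")
}

# independent oracle: splice the whole CDS out of the (mutated) chromosome,
# reverse-complement if needed, translate end-to-end with Biostrings, and
# diff the two protein strings
oracleClassifySnv <- function(pos, alt, tx, seqs) {
    s <- seqs[[tx@chrom]]
    mut <- s
    substr(mut, pos, pos) <- alt
    spliceCds <- function(str) {
        ex <- tx@exons
        pieces <- vapply(seq_along(ex), function(k)
            substr(str, BiocGenerics::start(ex)[k],
                   BiocGenerics::end(ex)[k]), character(1))
        cds <- paste(pieces, collapse = "")
        if (tx@strand == "-")
            cds <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cds)))
        cds
    }
    c0 <- spliceCds(s); c1 <- spliceCds(mut)
    if (c0 == c1) return(NULL)   # position not in CDS
    p0 <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(c0), no.init.codon = TRUE)), "")[[1]]
    p1 <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(c1), no.init.codon = TRUE)), "")[[1]]
    nt <- which(strsplit(c0, "")[[1]] != strsplit(c1, "")[[1]])
    codon <- (nt - 1L) %/% 3L + 1L
    refAa <- p0[codon]; altAa <- p1[codon]
    list(codonIndex = codon, refAa = refAa, altAa = altAa,
         consequence = if (refAa == altAa) "synonymous"
                       else if (altAa == "*") "nonsense" else "missense")
}

# minimal SomaticSet builder for recurrence tests
makeSomaticSet <- function(clone, keys, gene = NA, codon = NA, altAa = NA,
                           consequence = "missense") {
    n <- length(keys)
    parts <- strsplit(keys, ":")
    new("SomaticSet", clone = clone,
        variants = S4Vectors::DataFrame(
            chrom = vapply(parts, `[`, character(1), 1L),
            pos = as.integer(vapply(parts, `[`, character(1), 2L)),
            ref = vapply(parts, `[`, character(1), 3L),
            alt = vapply(parts, `[`, character(1), 4L),
            gene = rep_len(gene, n), codonIndex = rep_len(codon, n),
            refAa = rep_len("G", n), altAa = rep_len(altAa, n),
            consequence = rep_len(consequence, n),
            substitution = paste0("G", rep_len(codon, n),
                                  rep_len(altAa, n)),
            cloneVaf = rep(0.5, n), parentalVaf = rep(0, n),
            maxCounterVaf = rep(0, n)),
        provenance = list(criteria = "constructed"))
}

keysFor <- function(n, offset = 0L)
    paste("chr1", seq_len(n) + offset, "G", "A", sep = ":")

fitCurve <- function(data) {
    norm <- normalizeToVehicle(data)
    d <- norm[!norm$is_vehicle, ]
    fitDoseResponse(d$concentration_molar, d$reading)
}

assayDesign <- function() designDilutionSeries(50e-6, 15, minConc = 1.58e-9)
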