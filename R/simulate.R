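withPreservedSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Built-in toy genome for screen simulation
#'
#' One ~134 kb chromosome carrying 10 two-exon protein-coding genes (452
#' codons each), including a TUBA1B gene whose codons 47 and 142 encode
#' aspartate and glycine, so the hallmark tubulin resistance substitutions
#' (D47G/H, G142A/S) are reachable by single nucleotide changes. The genome
#' is fixed (internally seeded) so simulated screens are reproducible from
#' the simulation seed alone.
#'
#' @return list with \code{ref} (\code{DNAStringSet}), \code{transcripts}
#'   (named list of \linkS4class{TranscriptModel}), \code{codingMask}
#'   (logical per base) and \code{homopolymerRuns} (data.frame of runs of
#'   length >= 4: start, length, base, coding).
#' @export
toyGenome <- function() {
    withPreservedSeed(20210418L, {
        genes <- c("TUBA1B", paste0("GENE", sprintf("%02d", 2:10)))
        strands <- rep(c("+", "-"), 5L)
        nCodon <- 452L
        exon1len <- 600L
        intronLen <- 300L
        spacer <- 12000L
        margin <- 5000L
        cdsLen <- nCodon * 3L
        exon2len <- cdsLen - exon1len
        geneSpan <- cdsLen + intronLen
        L <- 2L * margin + 10L * geneSpan + 9L * spacer
        seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        aaOf <- Biostrings::GENETIC_CODE
        codons <- names(aaOf)
        sense <- codons[aaOf != "*"]
        makeCds <- function(gene) {
            body <- sample(sense[sense != "ATG"], nCodon - 2L,
                           replace = TRUE)
            if (gene == "TUBA1B") {
                body[47L - 1L] <- "GAC"   # Asp47 (body index offset by ATG)
                body[142L - 1L] <- "GGC"  # Gly142
            }
            paste(c("ATG", body, "TAA"), collapse = "")
        }
        transcripts <- vector("list", 10L)
        pos <- margin + 1L
        for (i in seq_len(10L)) {
            s1 <- pos
            e1 <- s1 + exon1len - 1L
            s2 <- e1 + intronLen + 1L
            e2 <- s2 + exon2len - 1L
            tx <- TranscriptModel(genes[i], paste0("TX_", genes[i]), "chr1",
                                  strands[i], c(s1, s2), c(e1, e2))
            cds <- makeCds(genes[i])
            cdsChars <- strsplit(cds, "")[[1]]
            gpos <- vapply(seq_len(cdsLen) - 1L,
                           function(o) cdsToGenomic(tx, o), integer(1))
            bases <- if (strands[i] == "-") compBase(cdsChars) else cdsChars
            seq[gpos] <- bases
            transcripts[[i]] <- tx
            pos <- e2 + spacer + 1L
        }
        names(transcripts) <- genes
        codingMask <- logical(L)
        for (tx in transcripts) {
            ex <- tx@exons
            for (k in seq_along(ex))
                codingMask[BiocGenerics::start(ex)[k]:
                           BiocGenerics::end(ex)[k]] <- TRUE
        }
        r <- rle(seq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$lengths >= 4L & starts > 1L
        runs <- data.frame(start = starts[keep], length = r$lengths[keep],
                           base = r$values[keep])
        runs$coding <- vapply(seq_len(nrow(runs)), function(k)
            any(codingMask[runs$start[k]:
                           (runs$start[k] + runs$length[k] - 1L)]),
            logical(1))
        list(ref = Biostrings::DNAStringSet(structure(
                 paste(seq, collapse = ""), names = "chr1")),
             transcripts = transcripts, codingMask = codingMask,
             homopolymerRuns = runs)
    })
}

#' Simulation configuration for a synthetic resistance screen
#'
#' Defaults describe the study conditions the package models: 6 resistant
#' clones from a hypermutator parental line, Poisson per-clone acquired
#' mutation burdens, a related clone pair sharing a 91-mutation lineage
#' branch, driver mutations planted at codons 142 (G142A homozygous, G142S
#' heterozygous) and 47 (D47G heterozygous, D47H at one-third of alleles) of
#' the TUBA1B-like gene in 4 of the 6 clones, mean coverage 80x, and a
#' counter-screen panel of 3 clones.
#'
#' @param seed RNG seed (required by \code{\link{simulateScreen}}).
#' @param nClones number of resistant clones.
#' @param lambdaPassenger Poisson mean of private acquired mutations per
#'   clone.
#' @param codingFraction probability a passenger lands in coding sequence.
#'   The default 0.0014 is the coding share of the exome-scale mutational
#'   target (~13.5 kb CDS over an implied ~10 Mb) the toy chromosome stands
#'   in for.
#' @param relatedPair list(i, j, branchSize): clones i and j share
#'   \code{branchSize} identical mutations (a pre-selection lineage branch).
#' @param driverGene gene receiving planted drivers.
#' @param driverSpec data.frame(clone, codon, altAa, zygosity); zygosity in
#'   \{1, 1/2, 1/3\} is the true VAF.
#' @param depthMean mean sequencing depth (per-site Poisson).
#' @param parentalErrorRate per-base rate of low-VAF artifact sites (true
#'   VAF below 0.01 in every sample).
#' @param backgroundHets number of heterozygous germline background variants
#'   carried by the parental line (and hence all clones).
#' @param counterScreenN counter-screen sample count.
#' @param filterFailRate fraction of non-driver records planted with one
#'   failing hard-filter annotation (QD, FS or MQ in its removal region).
#' @return list of class \code{ScreenSimConfig}.
#' @export
simulationConfig <- function(seed = NULL, nClones = 6L,
                             lambdaPassenger = 300,
                             codingFraction = 0.0014,
                             relatedPair = list(i = 1L, j = 3L,
                                                branchSize = 91L),
                             driverGene = "TUBA1B",
                             driverSpec = data.frame(
                                 clone = c(1L, 3L, 4L, 6L),
                                 codon = c(142L, 142L, 47L, 47L),
                                 altAa = c("A", "S", "G", "H"),
                                 zygosity = c(1, 0.5, 0.5, 1 / 3)),
                             depthMean = 80,
                             parentalErrorRate = 7e-4,
                             backgroundHets = 200L,
                             counterScreenN = 3L,
                             filterFailRate = 0.02) {
    stopifnot(lambdaPassenger > 0, nClones >= 1L,
              all(driverSpec$clone <= nClones),
              is.null(relatedPair) || relatedPair$branchSize >= 0L)
    okZyg <- vapply(driverSpec$zygosity, function(z)
        any(abs(z - c(1, 1 / 2, 1 / 3)) < 1e-9), logical(1))
    if (!all(okZyg))
        stop("config error: driver zygosity must be 1, 1/2 or 1/3")
    structure(list(seed = seed, nClones = as.integer(nClones),
                   lambdaPassenger = lambdaPassenger,
                   codingFraction = codingFraction,
                   relatedPair = relatedPair, driverGene = driverGene,
                   driverSpec = driverSpec, depthMean = depthMean,
                   parentalErrorRate = parentalErrorRate,
                   backgroundHets = as.integer(backgroundHets),
                   counterScreenN = as.integer(counterScreenN),
                   filterFailRate = filterFailRate),
              class = "ScreenSimConfig")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Find the single-nucleotide change producing a target substitution
#'
#' Searches the three positions of a codon for an SNV whose strand-aware
#' translation yields \code{altAa}; errors when no single change can reach
#' it.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param codon 1-based codon index.
#' @param altAa target amino-acid letter.
#' @param seqChar reference chromosome sequence as a single string.
#' @return list(pos, ref, alt, refAa).
#' @export
driverSnvForCodon <- function(tx, codon, altAa, seqChar) {
    if (codon < 1L || codon > nCodons(tx))
        stop("config error: codon ", codon, " beyond transcript ",
             tx@txId, " (", nCodons(tx), " codons)")
    offs <- (codon - 1L) * 3L + 0:2
    gpos <- vapply(offs, function(o) cdsToGenomic(tx, o), integer(1))
    basesG <- vapply(gpos, function(p) substr(seqChar, p, p), character(1))
    basesTx <- if (tx@strand == "-") compBase(basesG) else basesG
    refAa <- unname(Biostrings::GENETIC_CODE[paste(basesTx, collapse = "")])
    for (i in 1:3) for (b in setdiff(c("A", "C", "G", "T"), basesTx[i])) {
        cand <- basesTx
        cand[i] <- b
        if (unname(Biostrings::GENETIC_CODE[paste(cand, collapse = "")]) ==
            altAa) {
            altG <- if (tx@strand == "-") compBase(b) else b
            return(list(pos = gpos[i], ref = basesG[i], alt = altG,
                        refAa = refAa))
        }
    }
    stop("config error: substitution ", refAa, codon, altAa,
         " in ", tx@gene, " is not reachable by a single nucleotide change",
         " from codon ", paste(basesTx, collapse = ""))
}

#' Simulate a forward-genetics resistance screen
#'
#' Generates a full synthetic screen with the statistical structure the
#' analysis assumes -- parental heterozygous background variants, Poisson
#' per-clone private mutation burdens (SNVs with a 2:1
#' transition:transversion bias, 10 percent 1-bp indels anchored in
#' homopolymer runs of length >= 4), a shared lineage branch between one
#' clone pair, low-VAF parental artifact sites, planted driver SNVs at
#' requested codons/zygosities, and per-record planted hard-filter failures
#' -- then samples observed allele depths (depth ~ Poisson(depthMean), alt
#' reads ~ Binomial(depth, true VAF)) and writes VCF + FASTA + gene models
#' plus a JSON truth set. Output is byte-reproducible for a fixed seed.
#'
#' @param config a \code{\link{simulationConfig}} with a non-NULL seed.
#' @param dir output directory (created).
#' @return list: \code{panel} (\linkS4class{CloneScreenPanel}),
#'   \code{truth} (data.frame of all planted records: chrom, pos, ref, alt,
#'   sample, trueVaf, coding, driver, branch, plantedFail), \code{samples}
#'   (role list), \code{paths} (vcf, fasta, geneModels, truth),
#'   \code{genome}.
#' @export
simulateScreen <- function(config = simulationConfig(seed = 1L), dir) {
    if (is.null(config$seed)) stop("config error: seed is required")
    set.seed(config$seed)
    genome <- toyGenome()
    seqChar <- as.character(genome$ref[["chr1"]])
    L <- nchar(seqChar)
    codingPos <- which(genome$codingMask)
    noncodingPos <- which(!genome$codingMask)
    parental <- "parental"
    clones <- paste0("clone_", LETTERS[seq_len(config$nClones)])
    counters <- if (config$counterScreenN > 0L)
        paste0("counter_", seq_len(config$counterScreenN)) else character()
    samples <- c(parental, clones, counters)

    used <- new.env(hash = TRUE)
    takePos <- function(candidates) {
        repeat {
            p <- if (length(candidates) == 1L) candidates
                 else sample(candidates, 1L)
            k <- as.character(p)
            if (is.null(used[[k]])) { used[[k]] <- TRUE; return(p) }
        }
    }
    snvAt <- function(p) {
        refB <- substr(seqChar, p, p)
        altB <- if (stats::runif(1) < 2 / 3) TRANSITION[[refB]]
                else sample(TRANSVERSIONS[[refB]], 1L)
        list(pos = p, ref = refB, alt = altB)
    }
    runs <- genome$homopolymerRuns
    indelAt <- function(coding) {
        cand <- runs[runs$coding == coding, , drop = FALSE]
        if (!nrow(cand)) cand <- runs
        r <- cand[sample(nrow(cand), 1L), ]
        anchor <- r$start - 1L
        anchorB <- substr(seqChar, anchor, anchor)
        if (stats::runif(1) < 0.5)
            list(pos = anchor, ref = paste0(anchorB, r$base), alt = anchorB)
        else
            list(pos = anchor, ref = anchorB, alt = paste0(anchorB, r$base))
    }
    randomMutation <- function(coding) {
        if (stats::runif(1) < 0.1) {
            m <- indelAt(coding)
            if (!is.null(used[[as.character(m$pos)]]))
                return(randomMutation(coding))
            used[[as.character(m$pos)]] <- TRUE
            m
        } else {
            snvAt(takePos(if (coding) codingPos else noncodingPos))
        }
    }
    codingSpan <- function(pos, ref, alt) {
        if (nchar(ref) > 1L)               # deletion: bases removed
            any(genome$codingMask[(pos + 1L):(pos + nchar(ref) - 1L)])
        else if (nchar(alt) > 1L)          # insertion: flanking bases
            any(genome$codingMask[c(pos, min(pos + 1L, L))])
        else genome$codingMask[pos]        # SNV
    }

    rows <- list()
    addRecord <- function(m, carriers, vafs, driver = FALSE,
                          branch = FALSE, background = FALSE,
                          artifact = FALSE) {
        rows[[length(rows) + 1L]] <<- list(
            pos = m$pos, ref = m$ref, alt = m$alt, carriers = carriers,
            vafs = vafs, driver = driver, branch = branch,
            background = background, artifact = artifact)
    }

    tx <- genome$transcripts[[config$driverGene]]
    if (is.null(tx)) stop("config error: unknown driver gene ",
                          config$driverGene)
    for (k in seq_len(nrow(config$driverSpec))) {
        d <- config$driverSpec[k, ]
        m <- driverSnvForCodon(tx, d$codon, d$altAa, seqChar)
        used[[as.character(m$pos)]] <- TRUE
        addRecord(m[c("pos", "ref", "alt")], clones[d$clone], d$zygosity,
                  driver = TRUE)
    }
    for (b in seq_len(config$backgroundHets)) {
        m <- randomMutation(coding = stats::runif(1) <
                                mean(genome$codingMask))
        addRecord(m, samples, rep(0.5, length(samples)), background = TRUE)
    }
    nArt <- stats::rpois(1L, config$parentalErrorRate * L)
    for (a in seq_len(nArt)) {
        m <- snvAt(takePos(seq_len(L)))
        addRecord(m, samples,
                  stats::runif(length(samples), 0.001, 0.009),
                  artifact = TRUE)
    }
    zygLevels <- c(1, 0.5, 1 / 3)
    zygProbs <- c(0.1, 0.8, 0.1)
    for (ci in seq_len(config$nClones)) {
        n <- stats::rpois(1L, config$lambdaPassenger)
        for (k in seq_len(n)) {
            m <- randomMutation(stats::runif(1) < config$codingFraction)
            z <- sample(zygLevels, 1L, prob = zygProbs)
            addRecord(m, clones[ci], z)
        }
    }
    if (!is.null(config$relatedPair) && config$relatedPair$branchSize > 0L) {
        # the branch is the shared somatic-mutation count the relatedness
        # stage measures; that count is taken over coding somatic sets, so
        # branch mutations are planted in coding sequence
        pairClones <- clones[c(config$relatedPair$i, config$relatedPair$j)]
        for (k in seq_len(config$relatedPair$branchSize)) {
            m <- randomMutation(coding = TRUE)
            addRecord(m, pairClones, rep(0.5, 2L), branch = TRUE)
        }
    }
    nRec <- length(rows)
    variants <- data.frame(
        chrom = "chr1",
        pos = vapply(rows, function(r) as.integer(r$pos), integer(1)),
        ref = vapply(rows, function(r) r$ref, character(1)),
        alt = vapply(rows, function(r) r$alt, character(1)),
        qd = round(stats::runif(nRec, 10, 35), 2),
        fs = round(stats::runif(nRec, 0, 10), 3),
        mq = round(stats::runif(nRec, 50, 60), 2))
    trueVaf <- matrix(0, nRec, length(samples),
                      dimnames = list(NULL, samples))
    for (i in seq_len(nRec))
        trueVaf[i, rows[[i]]$carriers] <- rows[[i]]$vafs

    isDriver <- vapply(rows, function(r) r$driver, logical(1))
    plantedFail <- logical(nRec)
    nFail <- floor(config$filterFailRate * nRec)
    if (nFail > 0L) {
        failIdx <- sample(which(!isDriver), nFail)
        plantedFail[failIdx] <- TRUE
        for (i in failIdx) {
            field <- sample(c("qd", "fs", "mq"), 1L)
            variants[i, field] <- switch(field,
                qd = round(stats::runif(1, 0.1, 1.9), 2),
                fs = round(stats::runif(1, 61, 150), 3),
                mq = round(stats::runif(1, 20, 39), 2))
        }
    }

    dp <- matrix(stats::rpois(nRec * length(samples), config$depthMean),
                 nRec, length(samples), dimnames = list(NULL, samples))
    alt <- matrix(stats::rbinom(nRec * length(samples), as.vector(dp),
                                as.vector(trueVaf)),
                  nRec, length(samples), dimnames = list(NULL, samples))
    refD <- dp - alt
    gq <- matrix(as.integer(round(stats::runif(nRec * length(samples),
                                               30, 99))),
                 nRec, length(samples), dimnames = list(NULL, samples))
    called <- matrix(TRUE, nRec, length(samples),
                     dimnames = list(NULL, samples))

    panel <- CloneScreenPanel(variants, refDepth = refD, altDepth = alt,
                              depth = dp, gq = gq, called = called,
                              parental = parental, clones = clones,
                              counterScreen = counters)

    truth <- do.call(rbind, lapply(seq_len(nRec), function(i) {
        r <- rows[[i]]
        data.frame(chrom = "chr1", pos = as.integer(r$pos), ref = r$ref,
                   alt = r$alt, sample = r$carriers, trueVaf = r$vafs,
                   coding = codingSpan(r$pos, r$ref, r$alt),
                   driver = r$driver, branch = r$branch,
                   background = r$background, artifact = r$artifact,
                   plantedFail = plantedFail[i], stringsAsFactors = FALSE)
    }))

    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "screen.vcf"),
                  fasta = file.path(dir, "reference.fa"),
                  geneModels = file.path(dir, "gene_models.tsv"),
                  truth = file.path(dir, "truth.json"))
    writeScreenVcf(panel, paths$vcf)
    Biostrings::writeXStringSet(genome$ref, paths$fasta)
    writeGeneModels(genome$transcripts, paths$geneModels)
    jsonlite::write_json(list(
        seed = config$seed,
        samples = list(parental = parental, clones = clones,
                       counterScreen = counters),
        records = truth), paths$truth, auto_unbox = TRUE, digits = NA)

    list(panel = panel, truth = truth,
         samples = list(parental = parental, clones = clones,
                        counterScreen = counters),
         paths = paths, genome = genome)
}

#' Simulate a viability plate for one compound/sample curve
#'
#' Readings follow the normalized log-logistic model with multiplicative
#' Gaussian noise, \code{reading = model(conc) * (1 + N(0, noiseCv))},
#' truncated at 0; vehicle wells read at the 100 level with the same noise.
#' Uses the current RNG state (seed upstream for reproducibility).
#'
#' @param ic50 true IC50 (molar).
#' @param hill true Hill slope.
#' @param conc concentrations (molar), e.g.
#'   \code{designDilutionSeries(50e-6, 15, minConc = 1.58e-9)}.
#' @param replicates wells per concentration.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param compound,sample labels.
#' @param nVehicle vehicle (DMSO) wells.
#' @return data.frame in the viability-table layout (see
#'   \code{\link{readViabilityTable}}).
#' @export
simulateViability <- function(ic50, hill = 1, conc, replicates = 2L,
                              noiseCv = 0.02, compound = "compound",
                              sample = "sample", nVehicle = 4L) {
    stopifnot(noiseCv >= 0, all(conc > 0))
    grid <- expand.grid(replicate = seq_len(replicates),
                        concentration_molar = conc)
    mu <- doseResponseModel(grid$concentration_molar, log10(ic50), hill)
    reading <- pmax(0, mu * (1 + stats::rnorm(nrow(grid), 0, noiseCv)))
    wells <- data.frame(compound = compound, sample = sample,
                        concentration_molar = grid$concentration_molar,
                        replicate = grid$replicate, reading = reading,
                        is_vehicle = FALSE)
    veh <- data.frame(compound = compound, sample = sample,
                      concentration_molar = 0,
                      replicate = seq_len(nVehicle),
                      reading = pmax(0, 100 * (1 + stats::rnorm(nVehicle, 0,
                                                                noiseCv))),
                      is_vehicle = TRUE)
    rbind(wells, veh)
}
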