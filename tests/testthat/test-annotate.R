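# codon 142 fixture: CDS with codon 142 = GGC (Gly), as in the tubulin
# screen's hotspot
codon142Cds <- function(seed = 3) {
    set.seed(seed)
    cds <- randomCds(200L)
    substr(cds, 142L * 3L - 2L, 142L * 3L) <- "GGC"
    cds
}

test_that("codon 142 substitutions classify and translate correctly", {
    for (strand in c("+", "-")) {
        fx <- makeToyTx(codon142Cds(), strand = strand,
                        exonLens = c(300L, 300L), seed = 5)
        base1 <- cdsToGenomic(fx$tx, 423L)  # first base of codon 142
        base2 <- cdsToGenomic(fx$tx, 424L)
        base3 <- cdsToGenomic(fx$tx, 425L)
        flip <- function(b) if (strand == "-") chartr("ACGT", "TGCA", b) else b
        # GGC -> AGC : G142S missense
        cc <- classifyVariant("chrT", base1, flip("G"), flip("A"), fx$tx,
                              fx$seqs)
        expect_equal(cc$consequence, "missense")
        expect_equal(cc$codonIndex, 142L)
        expect_equal(cc$refAa, "G")
        expect_equal(cc$altAa, "S")
        expect_equal(cc$substitution, "G142S")
        # GGC -> GCC : G142A missense
        cc <- classifyVariant("chrT", base2, flip("G"), flip("C"), fx$tx,
                              fx$seqs)
        expect_equal(cc$altAa, "A")
        expect_equal(cc$substitution, "G142A")
        # GGC -> GGT : synonymous
        cc <- classifyVariant("chrT", base3, flip("C"), flip("T"), fx$tx,
                              fx$seqs)
        expect_equal(cc$consequence, "synonymous")
        expect_equal(cc$codonIndex, 142L)
    }
})

test_that("CDS offsets count coding bases in transcription direction", {
    fx <- makeToyTx(randomCds(150L), strand = "+", seed = 9)
    g <- BiocGenerics::start(fx$tx@exons)[1L]
    expect_equal(cdsOffset(fx$tx, g + 423L), 423L)
    rv <- makeToyTx(randomCds(150L), strand = "-", seed = 9)
    expect_equal(cdsOffset(rv$tx, BiocGenerics::end(rv$tx@exons)[1L]), 0L)
    # intronic position has no offset
    two <- makeToyTx(randomCds(100L), strand = "+", exonLens = c(150L, 150L),
                     intronLen = 30L, seed = 2)
    intronPos <- BiocGenerics::end(two$tx@exons)[1L] + 10L
    expect_true(is.na(cdsOffset(two$tx, intronPos)))
    # cdsToGenomic inverts cdsOffset everywhere
    for (o in c(0L, 1L, 149L, 150L, 299L))
        expect_equal(cdsOffset(two$tx, cdsToGenomic(two$tx, o)), o)
})

test_that("indels classify by frame and splice sites by intron proximity", {
    fx <- makeToyTx(randomCds(100L), strand = "+", exonLens = c(150L, 150L),
                    intronLen = 30L, seed = 4)
    s <- fx$seqs[["chrT"]]
    ex1end <- BiocGenerics::end(fx$tx@exons)[1L]
    inCds <- BiocGenerics::start(fx$tx@exons)[1L] + 30L
    # 1-bp deletion inside CDS: length change not divisible by 3
    del <- classifyVariant("chrT", inCds, substr(s, inCds, inCds + 1L),
                           substr(s, inCds, inCds), fx$tx, fx$seqs)
    expect_equal(del$consequence, "frameshift")
    # 3-bp deletion: in-frame
    del3 <- classifyVariant("chrT", inCds, substr(s, inCds, inCds + 3L),
                            substr(s, inCds, inCds), fx$tx, fx$seqs)
    expect_equal(del3$consequence, "inframe_indel")
    expect_false(is.na(del3$codonIndex))
    # SNV 2 bases into the intron: splice; 3 bases in: noncoding
    p2 <- ex1end + 2L
    b2 <- substr(s, p2, p2)
    sp <- classifyVariant("chrT", p2, b2, setdiff(c("A", "C", "G", "T"),
                                                  b2)[1L], fx$tx, fx$seqs)
    expect_equal(sp$consequence, "splice")
    p3 <- ex1end + 3L
    b3 <- substr(s, p3, p3)
    nc <- classifyVariant("chrT", p3, b3, setdiff(c("A", "C", "G", "T"),
                                                  b3)[1L], fx$tx, fx$seqs)
    expect_equal(nc$consequence, "noncoding")
    # coding definitions: noncoding excluded, splice configurable
    expect_true(isCoding("missense"))
    expect_false(isCoding("noncoding"))
    expect_true(isCoding("splice"))
    expect_false(isCoding("splice",
                          filterConfig(countSpliceAsCoding = FALSE)))
    expect_equal(isCoding(c("synonymous", "nonsense", "frameshift",
                            "inframe_indel", "noncoding")),
                 c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("a wrong ref allele raises a reference-mismatch error", {
    fx <- makeToyTx(randomCds(60L), seed = 6)
    p <- cdsToGenomic(fx$tx, 30L)
    actual <- substr(fx$seqs[["chrT"]], p, p)
    wrong <- setdiff(c("A", "C", "G", "T"), actual)[1L]
    other <- setdiff(c("A", "C", "G", "T"), c(actual, wrong))[1L]
    expect_error(classifyVariant("chrT", p, wrong, other, fx$tx, fx$seqs),
                 "reference mismatch")
})

test_that("classification matches the whole-CDS translation oracle on random SNVs", {
    set.seed(101)
    nChecked <- 0L
    for (rep in 1:25) {
        strand <- sample(c("+", "-"), 1L)
        nEx <- sample(1:3, 1L)
        nCod <- sample(40:120, 1L)
        lens <- rep(nCod * 3L %/% nEx, nEx)
        lens[nEx] <- nCod * 3L - sum(lens[-nEx])
        fx <- makeToyTx(randomCds(nCod), strand = strand, exonLens = lens,
                        intronLen = 25L)
        s <- fx$seqs[["chrT"]]
        for (k in 1:10) {
            off <- sample(nCod * 3L, 1L) - 1L
            p <- cdsToGenomic(fx$tx, off)
            ref <- substr(s, p, p)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
            got <- classifyVariant("chrT", p, ref, alt, fx$tx, fx$seqs)
            want <- oracleClassifySnv(p, alt, fx$tx, fx$seqs)
            expect_equal(got$codonIndex, want$codonIndex)
            expect_equal(got$refAa, want$refAa)
            expect_equal(got$altAa, want$altAa)
            expect_equal(got$consequence, want$consequence)
            nChecked <- nChecked + 1L
        }
    }
    expect_gte(nChecked, 250L)
})

test_that("a transcript and its reverse-complement mirror classify mirrored variants identically", {
    set.seed(33)
    for (rep in 1:5) {
        fx <- makeToyTx(randomCds(60L), strand = "+",
                        exonLens = c(90L, 90L), intronLen = 20L)
        s <- fx$seqs[["chrT"]]
        L <- nchar(s)
        mirrorSeq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        ex <- fx$tx@exons
        mStarts <- rev(L - BiocGenerics::end(ex) + 1L)
        mEnds <- rev(L - BiocGenerics::start(ex) + 1L)
        mtx <- TranscriptModel(fx$tx@gene, "TX_M", "chrT", "-",
                               mStarts, mEnds)
        for (k in 1:10) {
            off <- sample(180L, 1L) - 1L
            p <- cdsToGenomic(fx$tx, off)
            ref <- substr(s, p, p)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
            a <- classifyVariant("chrT", p, ref, alt, fx$tx, fx$seqs)
            mp <- L - p + 1L
            b <- classifyVariant("chrT", mp, chartr("ACGT", "TGCA", ref),
                                 chartr("ACGT", "TGCA", alt), mtx,
                                 c(chrT = mirrorSeq))
            expect_equal(b$codonIndex, a$codonIndex)
            expect_equal(b$refAa, a$refAa)
            expect_equal(b$altAa, a$altAa)
            expect_equal(b$consequence, a$consequence)
        }
    }
})

test_that("annotateVariants maps panel records to their containing gene", {
    fx <- makeToyTx(codon142Cds(), strand = "+", seed = 5)
    p <- cdsToGenomic(fx$tx, 423L)
    v <- data.frame(chrom = "chrT", pos = c(p, 5L),
                    ref = c("G", substr(fx$seqs[["chrT"]], 5L, 5L)),
                    alt = c("A", "A"))
    v$alt[2] <- setdiff(c("A", "C", "G", "T"), v$ref[2])[1L]
    cons <- annotateVariants(v, list(GENEX = fx$tx), fx$seqs)
    expect_equal(cons$gene[1L], "GENEX")
    expect_equal(cons$substitution[1L], "G142S")
    expect_equal(cons$consequence[2L], "noncoding")
    expect_true(is.na(cons$gene[2L]))
})
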