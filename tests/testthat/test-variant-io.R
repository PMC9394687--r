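test_that("a 3-sample VCF with two biallelic sites maps directly onto a panel", {
    recs <- c(
        "chr1\t10\t.\tG\tA\t100\tPASS\tQD=25.1;FS=1.2;MQ=60\tGT:AD:DP:GQ\t0/1:60,40:100:99\t0/0:80,0:80:90\t./.:.:.:.",
        "chr1\t20\t.\tC\tT\t80\tPASS\tFS=0;MQ=59\tGT:AD:DP:GQ\t0/0:50,0:50:60\t0/1:30,30:60:40\t0/0:70,0:70:99")
    path <- writeTestVcf(recs, c("par", "cloneA", "cloneB"))
    panel <- readScreenVcf(path, parental = "par",
                           clones = c("cloneA", "cloneB"))
    expect_s4_class(panel, "CloneScreenPanel")
    expect_equal(dim(panel), c(2L, 3L))
    expect_equal(parentalName(panel), "par")
    expect_equal(cloneNames(panel), c("cloneA", "cloneB"))
    expect_equal(variantKeys(panel), c("chr1:10:G:A", "chr1:20:C:T"))
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(panel))
    expect_equal(mc$qd, c(25.1, NA))        # absent INFO is missing, not 0
    expect_equal(mc$fs, c(1.2, 0))
    ad <- SummarizedExperiment::assay(panel, "altDepth")
    expect_equal(unname(ad[, "par"]), c(40L, 0L))
    expect_false(SummarizedExperiment::assay(panel, "called")[1, "cloneB"])
    v <- vaf(panel)
    expect_equal(unname(v[1, "par"]), 0.4)
    expect_true(is.na(v[1, "cloneB"]))      # uncalled sample
})

test_that("multi-allelic sites split into biallelic records conserving alt count", {
    recs <- c(
        "chr1\t20\t.\tC\tA,T\t80\tPASS\tQD=20;FS=0;MQ=59\tGT:AD:DP:GQ\t1/2:10,20,30:60:50\t0/1:50,10,0:60:40",
        "chr1\t40\t.\tG\tA\t90\tPASS\tQD=21;FS=0;MQ=58\tGT:AD:DP:GQ\t0/1:30,30:60:70\t0/0:60,0:60:80",
        "chr1\t50\t.\tA\tC,G,T\t70\tPASS\tQD=18;FS=1;MQ=55\tGT:AD:DP:GQ\t1/2:5,10,15,20:50:30\t0/1:40,2,3,4:50:22")
    path <- writeTestVcf(recs, c("s1", "s2"))
    panel <- readScreenVcf(path, parental = "s1", clones = "s2")
    expect_equal(nrow(panel), 2L + 1L + 3L)  # sum of per-site alt counts
    k <- variantKeys(panel)
    expect_setequal(k[startsWith(k, "chr1:20")],
                    c("chr1:20:C:A", "chr1:20:C:T"))
    ad <- SummarizedExperiment::assay(panel, "altDepth")
    expect_equal(unname(ad[k == "chr1:20:C:A", "s1"]), 20L)  # allele-specific
    expect_equal(unname(ad[k == "chr1:20:C:T", "s1"]), 30L)
})

test_that("role map naming a sample missing from the header is a configuration error", {
    path <- writeTestVcf(
        "chr1\t10\t.\tG\tA\t100\tPASS\tQD=25\tGT:AD:DP:GQ\t0/1:60,40:100:99",
        "only")
    expect_error(readScreenVcf(path, parental = "only", clones = "ghost"),
                 "ghost")
})

test_that("VAF follows allele-depth arithmetic with an explicit indeterminate state", {
    expect_equal(computeVaf(60, 40), 0.4)
    expect_equal(computeVaf(100, 0), 0)
    expect_true(is.na(computeVaf(0, 0)))
    # complement symmetry and range, over random depths
    set.seed(7)
    r <- rpois(200, 30); a <- rpois(200, 10)
    v <- computeVaf(r, a)
    defined <- !is.na(v)
    expect_true(all(v[defined] >= 0 & v[defined] <= 1))
    expect_equal(v[defined], 1 - computeVaf(a, r)[defined])
})

test_that("a panel round-trips through VCF with identical keys, depths and annotations", {
    set.seed(11)
    n <- 25L
    samples <- c("par", "cA", "cB")
    variants <- data.frame(
        chrom = "chr1", pos = sort(sample(1000:9999, n)),
        ref = sample(c("G", "C", "GAT"), n, replace = TRUE),
        alt = "A",
        qd = round(runif(n, 2, 35), 2), fs = round(runif(n, 0, 50), 2),
        mq = round(runif(n, 40, 60), 2))
    variants$qd[3] <- NA   # missing stays missing through the round trip
    m <- function() matrix(rpois(n * 3, 40), n, 3,
                           dimnames = list(NULL, samples))
    called <- matrix(TRUE, n, 3, dimnames = list(NULL, samples))
    called[5, "cB"] <- FALSE
    panel <- CloneScreenPanel(variants, refDepth = m(), altDepth = m(),
                              depth = matrix(200L, n, 3,
                                             dimnames = list(NULL, samples)),
                              gq = m(), called = called, parental = "par",
                              clones = c("cA", "cB"))
    path <- tempfile(fileext = ".vcf")
    writeScreenVcf(panel, path)
    back <- readScreenVcf(path, "par", c("cA", "cB"))
    o1 <- order(variantKeys(panel)); o2 <- order(variantKeys(back))
    expect_equal(variantKeys(back)[o2], variantKeys(panel)[o1])
    for (a in c("refDepth", "altDepth", "depth", "gq")) {
        m1 <- SummarizedExperiment::assay(panel, a)[o1, samples]
        m2 <- SummarizedExperiment::assay(back, a)[o2, samples]
        m1[!called[o1, ]] <- NA   # uncalled depths are not representable
        expect_equal(unname(m2), unname(m1), info = a)
    }
    mc1 <- S4Vectors::mcols(SummarizedExperiment::rowRanges(panel))[o1, ]
    mc2 <- S4Vectors::mcols(SummarizedExperiment::rowRanges(back))[o2, ]
    expect_equal(mc2$qd, mc1$qd)
    expect_equal(mc2$fs, mc1$fs)
    expect_equal(mc2$mq, mc1$mq)
    expect_equal(SummarizedExperiment::assay(back, "called")[o2, samples],
                 called[o1, ])
})

test_that("variants are reduced to minimal representation on read", {
    n <- normalizeVariants(c("chr1", "chr1", "chr1"),
                           c(100L, 200L, 300L),
                           c("CTT", "TGG", "G"),
                           c("CT", "TCG", "A"))
    expect_equal(n$ref, c("CT", "G", "G"))
    expect_equal(n$alt, c("C", "C", "A"))
    expect_equal(n$pos, c(100L, 201L, 300L))
})

test_that("reference FASTA reading uppercases and tokenizes names", {
    path <- tempfile(fileext = ".fa")
    writeLines(c(">chr1 some description", "acgtACGT",
                 ">chr2 other", "GGGG"), path)
    ref <- readReference(path)
    expect_equal(names(ref), c("chr1", "chr2"))
    expect_equal(as.character(ref[["chr1"]]), "ACGTACGT")
    empty <- tempfile(fileext = ".fa")
    file.create(empty)
    expect_warning(r0 <- readReference(empty), "empty")
    expect_length(r0, 0)
})

test_that("gene-model TSV parses, validates and round-trips", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("gene\ttranscript\tchrom\tstrand\tcds_starts\tcds_ends",
                 "G1\tT1\tchr1\t+\t101,501\t400,626",
                 "G2\tT2\tchr1\t-\t1001\t1426"), path)
    txs <- readGeneModels(path)
    expect_named(txs, c("G1", "G2"))
    expect_equal(cdsLength(txs$G1), 300L + 126L)
    expect_equal(nCodons(txs$G1), 142L)
    # minus strand: codon order follows transcription direction
    expect_equal(cdsOffset(txs$G2, 1426L), 0L)
    expect_equal(cdsOffset(txs$G2, 1001L), 425L)
    out <- tempfile(fileext = ".tsv")
    writeGeneModels(txs, out)
    expect_equal(readLines(out), readLines(path))

    bad1 <- tempfile(); bad2 <- tempfile(); bad3 <- tempfile()
    writeLines(c("gene\ttranscript\tchrom\tstrand\tcds_starts\tcds_ends",
                 "G1\tT1\tchr1\t+\t500\t400"), bad1)
    expect_error(readGeneModels(bad1), "end < start")
    writeLines(c("gene\ttranscript\tchrom\tstrand\tcds_starts\tcds_ends",
                 "G1\tT1\tchr1\t+\t101\t420"), bad2)
    expect_error(readGeneModels(bad2), "divisible by 3")
    writeLines(c("gene\ttranscript\tchrom\tstrand\tcds_starts\tcds_ends",
                 "G1\tT1\tchr1\t+\t101\t400",
                 "G1\tT1b\tchr1\t+\t601\t900"), bad3)
    expect_error(readGeneModels(bad3), "one canonical transcript")
})
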