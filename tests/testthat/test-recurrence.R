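test_that("shared counts follow set intersection of variant keys", {
    a <- makeSomaticSet("A", keysFor(10L))
    b <- makeSomaticSet("B", keysFor(10L, offset = 5L))  # overlap of 5
    expect_equal(sharedCount(a, b), 5L)
    expect_equal(sharedCount(a, makeSomaticSet("C", keysFor(4L, 100L))), 0L)
    expect_equal(sharedCount(a, a), 10L)
    # symmetry and bound, random sets
    set.seed(12)
    for (k in 1:10) {
        x <- makeSomaticSet("X", sample(keysFor(40L), sample(5:30, 1)))
        y <- makeSomaticSet("Y", sample(keysFor(40L), sample(5:30, 1)))
        expect_equal(sharedCount(x, y), sharedCount(y, x))
        expect_lte(sharedCount(x, y),
                   min(nrow(somaticVariants(x)), nrow(somaticVariants(y))))
    }
})

screenLikeSets <- function() {
    # six clones: A and C share 91 keys, all other pairwise sharing <= 11
    branch <- keysFor(91L)
    common <- keysFor(11L, offset = 2000L)   # shared by B and D only
    list(
        makeSomaticSet("A", c(branch, keysFor(30L, 3000L))),
        makeSomaticSet("B", c(common, keysFor(25L, 4000L))),
        makeSomaticSet("C", c(branch, keysFor(28L, 5000L))),
        makeSomaticSet("D", c(common, keysFor(31L, 6000L))),
        makeSomaticSet("E", keysFor(27L, 7000L)),
        makeSomaticSet("F", keysFor(29L, 8000L)))
}

test_that("relatedness groups the 91-mutation pair and leaves others singletons", {
    sets <- screenLikeSets()
    rel <- relatedness(sets, shareThreshold = 20)
    m <- sharedCounts(rel)
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)),
                 vapply(sets, function(s) nrow(somaticVariants(s)),
                        integer(1)))
    expect_equal(m["A", "C"], 91L)
    off <- m[upper.tri(m)]
    expect_true(all(off[off != 91L] <= 11L))
    grp <- relatedGroups(rel)
    expect_equal(sort(vapply(grp, length, integer(1))), c(1, 1, 1, 1, 2))
    expect_true(any(vapply(grp, function(g) setequal(g, c("A", "C")),
                           logical(1))))
    # higher threshold dissolves the pair
    rel100 <- relatedness(sets, shareThreshold = 100)
    expect_true(all(vapply(relatedGroups(rel100), length, integer(1)) == 1))
    # identical clones group at any threshold up to the set size
    twins <- list(makeSomaticSet("T1", keysFor(15L)),
                  makeSomaticSet("T2", keysFor(15L)))
    expect_equal(vapply(relatedGroups(relatedness(twins, 15)), length,
                        integer(1)), 2L)
    expect_error(relatedness(list(makeSomaticSet("X", keysFor(3)),
                                  makeSomaticSet("X", keysFor(3))), 5),
                 "duplicate")
})

test_that("gene recurrence counts clones raw and collapsed over related groups", {
    mk <- function(clone, keys, gene, codon = NA_integer_,
                   altAa = NA_character_)
        makeSomaticSet(clone, keys, gene = gene, codon = codon,
                       altAa = altAa)
    # relatedness: A+C related via 91 shared keys in GENE_BG
    branch <- keysFor(91L, 9000L)
    sets <- list(
        mk("A", c(branch, "chr1:1:G:A"), gene = "GENE_BG"),
        mk("B", "chr1:2:G:A", gene = "TUBX"),
        mk("C", c(branch, "chr1:3:G:A"), gene = "GENE_BG"),
        mk("D", "chr1:4:G:A", gene = "TUBX"),
        mk("E", "chr1:5:G:A", gene = "OTHER"),
        mk("F", "chr1:6:G:A", gene = "TUBX"))
    # add a TUBX hit in A so TUBX is mutated in {A, B, D, F}: raw 4
    sets[[1]]@variants <- rbind(sets[[1]]@variants,
                                mk("A", "chr1:7:G:A", gene = "TUBX")@variants)
    rel <- relatedness(sets, 20)
    rep <- geneRecurrence(sets, rel)
    gt <- as.data.frame(geneTable(rep))
    expect_equal(gt$rawCount[gt$gene == "TUBX"], 4L)       # four of six
    expect_equal(gt$collapsedCount[gt$gene == "TUBX"], 4L) # A,B,D,F unrelated
    expect_equal(gt$rawCount[gt$gene == "GENE_BG"], 2L)    # related pair only
    expect_equal(gt$collapsedCount[gt$gene == "GENE_BG"], 1L)
    # with an unreachable threshold no clones are related: collapsed == raw
    relInf <- relatedness(sets, shareThreshold = Inf)
    gtInf <- as.data.frame(geneTable(geneRecurrence(sets, relInf)))
    expect_equal(gtInf$collapsedCount, gtInf$rawCount)
    # collapsing never increases counts
    expect_true(all(gt$collapsedCount <= gt$rawCount))
})

test_that("codon recurrence records distinct substitutions from unrelated clones", {
    mk <- function(clone, key, altAa)
        makeSomaticSet(clone, key, gene = "TUBX", codon = 142L,
                       altAa = altAa)
    sets <- list(mk("A", "chr1:10:G:A", "A"),
                 mk("B", "chr1:11:G:C", "S"),
                 makeSomaticSet("C", "chr1:500:G:A", gene = "OTHER"))
    rel <- relatedness(sets, 20)
    ct <- as.data.frame(codonTable(geneRecurrence(sets, rel)))
    row <- ct[ct$gene == "TUBX" & ct$codonIndex == 142L, ]
    expect_equal(row$substitutions, "A/S")    # two distinct substitutions
    expect_equal(row$nUnrelatedClones, 2L)
    expect_true(row$recurrent)
    # same codon hit only within a related pair is not recurrent
    branch <- keysFor(50L, 900L)
    rsets <- list(
        makeSomaticSet("A", c(branch, "chr1:10:G:A"), gene = "TUBX",
                       codon = 142L, altAa = "A"),
        makeSomaticSet("C", c(branch, "chr1:11:G:C"), gene = "TUBX",
                       codon = 142L, altAa = "S"))
    rrel <- relatedness(rsets, 20)
    rct <- as.data.frame(codonTable(geneRecurrence(rsets, rrel)))
    expect_false(any(rct$recurrent[rct$codonIndex == 142L]))
})

test_that("candidate ranking applies the cutoff and stated tie-breaks", {
    mkGene <- function(clone, gene, codon = NA_integer_,
                       altAa = NA_character_, key)
        makeSomaticSet(clone, key, gene = gene, codon = codon,
                       altAa = altAa)
    # two genes in 4 of 6 clones; GENE_R has a recurrent codon, GENE_N not;
    # FILLER is mutated in only 2 clones
    sets <- lapply(1:6, function(i) {
        if (i <= 4) {
            s <- makeSomaticSet(LETTERS[i], paste0("chr1:", 200 + i, ":G:A"),
                                gene = "GENE_R", codon = 50L,
                                altAa = c("A", "S", "G", "H")[i])
            s@variants <- rbind(
                s@variants,
                makeSomaticSet(LETTERS[i], paste0("chr1:", 300 + i, ":G:A"),
                               gene = "GENE_N",
                               codon = as.integer(10L + i),
                               altAa = "V")@variants)
            s
        } else {
            makeSomaticSet(LETTERS[i], paste0("chr1:", 100 + i, ":G:A"),
                           gene = "FILLER")
        }
    })
    rel <- relatedness(sets, 20)   # nobody related
    rep <- geneRecurrence(sets, rel)
    top <- rankCandidates(rep, minClones = 4L)
    expect_equal(top, c("GENE_R", "GENE_N"))  # recurrent codon breaks tie
    expect_equal(rankCandidates(rep, minClones = 7L), character())
    expect_equal(geneTable(rep)$gene[1L], "GENE_R")
})
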