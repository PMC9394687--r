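Package: ForwardScreen
Title: Forward-Genetics Resistance Screen Analysis from Variant Calls to
    Candidate Targets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of forward-genetics resistance screens performed in
    hypermutator (mismatch-repair deficient) cancer cell lines. Starting
    from multi-sample variant calls (VCF) for a parental line,
    compound-resistant clones and a counter-screen panel, the package
    applies site-level hard filters, derives per-clone acquired somatic
    mutation sets from variant allele frequency criteria, annotates
    variants to codon-resolution coding consequences, quantifies clone
    relatedness by shared mutations, and ranks candidate target genes by
    gene- and codon-level recurrence across independent clones. It also
    fits normalized log-logistic dose-response curves (IC50, Hill slope)
    to viability data and computes fold-resistance, and ships a synthetic
    screen simulator (clone exomes with planted drivers plus truth sets,
    and viability plates) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Genetics, VariantAnnotation, SomaticMutation,
    Pharmacogenomics
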