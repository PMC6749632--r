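Package: pedcase
Title: Pedigree and Breakpoint Forensics for Isolated Congenital Disease Cases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational forensics for an isolated congenital disease case
    in a livestock population: pedigree kinship and inbreeding by the tabular
    recursion, detection of ancestors common to the paternal and maternal
    lineages of a proband, gene-dropping estimation of ancestral genetic
    contributions with an exact recursion cross-check, expected
    recessive-homozygote case counts and a Poisson zero-observation argument
    for rejecting recessive inheritance, progeny mortality screens,
    private heterozygous variant prioritization against a control panel,
    structural-variant junction classification (microhomology, duplication,
    deletion; MMBIR-like vs NHEJ-like repair signatures), dotplot word
    matching, read-depth window profiles with copy-number flags, and quadrat
    skin morphometry summaries. A synthetic-data module generates looped
    pedigrees with planted carrier ancestors, variant tables with planted
    private candidates, junction sequences with configurable repair
    signatures, and depth profiles, so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
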