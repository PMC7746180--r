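Package: redoxDE
Title: Pattern Analysis of Redox-Responsive Differential Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Analysis pipeline for RNA-seq experiments that probe
    oxidation-dependent transcription-factor activity with a two-genotype
    (wild-type versus redox-insensitive mutant) by two-treatment (basal
    versus oxidative stress) design. Provides negative-binomial conditional
    exact tests per pairwise comparison with Benjamini-Hochberg correction,
    discretisation of the four comparisons into -1/0/1 pattern codes,
    enumeration and selection of oxidation-responsive gene clusters, IUPAC
    consensus motif scanning of promoter windows with a mismatch budget,
    hypergeometric gene-set enrichment and overlap tests, ChIP peak
    filtering by fold enrichment over control with promoter assignment and
    genomic-feature classification, and a seeded synthetic-data generator
    (counts with planted pattern codes, promoters with planted motifs,
    peaks with planted enrichment) so that every stage can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
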