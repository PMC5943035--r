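Package: k9te
Title: Comparative Analysis of H3K9me3-Mediated Transposable Element Silencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing H3K9me3-mediated
    transposable element (TE) silencing between two closely related species.
    From per-individual ChIP and Input fragment intervals and per-species
    RepeatMasker-style TE annotations, the package calls broad H3K9me3
    domains, constructs orthologous regions via reciprocal-best chain
    lifting with minimum-match and uniqueness rules, filters by k-mer
    mappability, tests regions for differential enrichment with a negative
    binomial Wald engine, classifies TE silencing as shared or
    species-enriched, and associates divergence in TE silencing with
    neighboring gene expression divergence. A synthetic two-genome cohort
    simulator with full ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    limma,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
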