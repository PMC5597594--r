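Package: polytrans
Title: Polysome-Profiling 3' RNA-Seq and iCLIP Differential Translation Analysis
Version: 0.1.0
Authors@R: person("Polytrans", "Developers", role = c("aut", "cre"),
    email = "polytrans@example.org")
Description: Analysis pipeline for polysome-fractionated 3'-end RNA sequencing
    and iCLIP data. Provides barcode demultiplexing, UMI-based PCR
    deduplication and rule-based poly(A)-tract trimming of 3'-end reads; a
    from-scratch negative-binomial GLM framework (median-of-ratios size
    factors, moment/trend dispersion estimation, IRLS fitting, Wald and
    likelihood-ratio tests, Benjamini-Hochberg adjustment); polysome
    distribution analysis across sucrose-gradient fractions with per-fraction
    post-hoc tests and the RiboLoad heavy-polysome statistic; iCLIP crosslink
    extraction, feature annotation and permutation-based peak enrichment; and
    an integration layer that classifies genes by changes in mRNA abundance
    and translation. A synthetic-data generator with recorded ground truth
    stands in for deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
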