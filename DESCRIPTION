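Package: pfomics
Title: Gene-Signature Tumor Group Classification and Multi-Sample
    Single-Nucleus Multi-Omic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for molecular-group classification of ependymal tumor
    expression profiles using group-exclusive gene signatures and a
    running-sum enrichment statistic with a gene-randomization permutation
    test; a multi-sample differential expression and differential
    accessibility framework for single-nucleus cohorts that applies
    per-sample population-versus-rest tests, expression and
    population-abundance inclusion filters, Fisher's method to combine
    p-values across samples, and Benjamini-Hochberg false discovery rates;
    chromatin-accessibility utilities (peak-set union, peak-width
    filtering, gene activity scores, enhancer concordance, motif-deviation
    tests) and construction of directed transcription-factor regulatory
    networks from differentially accessible binding sites near gene loci.
    Includes synthetic multi-omic cohort simulators with planted ground
    truth so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
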