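Package: ribostress
Title: Cross-Species Analysis of Ribosomal Protein Gene Dysregulation in
    Chronic Stress Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting conserved ribosomal-protein-gene (RPG)
    dysregulation in stress and depression transcriptomes across species.
    Implements pseudogene-aware read assignment against a composite
    reference by exact unique matching, differential-expression
    summarisation with covariate adjustment and Benjamini-Hochberg
    correction, hypergeometric gene-family overlap enrichment with
    mouse/human symbol harmonisation, seeded signed Spearman co-expression
    networks, Gene Ontology theme clustering, and a negative-binomial
    simulator that generates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
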