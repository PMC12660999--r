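Package: multiomod
Title: Pseudobulk Multiome Module Detection and Regulatory Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted pseudobulk construction from single-cell RNA and ATAC
    count matrices, co-expression and co-accessibility module detection via
    topological-overlap clustering with specific/mixed classification and tau
    specificity, motif and functional-category enrichment, module-graph
    consensus and community analysis, a transparent distance-decay TF-target
    interaction and influence scorer, simplified pseudobulk negative-binomial
    differential testing, and knockdown-evaluation statistics. Ships a
    synthetic multiome generator with planted ground truth (cell types,
    modules, TF targets, open chromatin regions, knockdown effects) so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    S4Vectors,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
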