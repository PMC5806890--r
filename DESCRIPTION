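Package: coexEnsemble
Title: Ensemble Inference of Gene Co-Expression Networks from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers genome-wide gene co-expression networks from RNA-seq
    count matrices by running three base inference algorithms (weighted
    correlation with topological overlap, shrinkage Gaussian graphical
    models, and bagged conservative causal core mutual-information
    networks) over six normalizations of the data, filtering each initial
    network at a permutation-derived confidence cutoff, and combining the
    resulting networks by two-step unweighted voting with confidence
    re-scoring. Includes construction of gold-standard positive and
    negative functional gene links from ontology, pathway and network
    inputs, fold-enrichment and gene-centric function-prediction (CAFA
    style) evaluation, and a synthetic-data generator so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    edgeR,
    DESeq2,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
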