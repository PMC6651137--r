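Package: ndprio
Title: Network Diffusion for Multi-Omics Gene Prioritization and Disease-Module Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative prioritization of disease genes from multi-layer
    (genomics / epigenomics / transcriptomics) evidence on a protein-protein
    interaction network. Implements network diffusion on the symmetrically
    normalized adjacency operator, a composite multi-omics diffusion score with
    permutation significance, extraction of significantly connected gene
    modules by network resampling, topological community detection with Newman
    modularity, hypergeometric overlap and enrichment statistics, and a
    synthetic-data generator with planted modules for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    fgsea,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
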