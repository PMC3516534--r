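Package: internode
Title: Crosstalk Discovery Between Two Gene Systems from Multi-Evidence
    Functional Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a filtered multi-evidence functional interactome from
    protein-protein interactions, protein complexes, metabolic reaction
    adjacency and pathway co-membership, identifies and ranks "internode"
    (linker) genes that simultaneously connect two biological systems
    (e.g. the insulin signalling cascade and the mitochondrial proteome),
    and evaluates candidate sets with chi-square gene-set enrichment,
    expression GSEA with permutation nulls, gene-based GWAS enrichment
    scans, and a summary-statistic multi-SNP genetic risk score.
    Degree-preserving network rewiring and size-matched random gene sets
    provide empirical null distributions throughout, and a synthetic-data
    module generates every input format with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
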