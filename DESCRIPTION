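Package: cgpnet
Title: Network-Assisted GWAS Analysis with Exact Circular Genomic Permutation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines GWAS SNP-level P-values and a protein-protein
    interaction (PPI) network to identify gene modules jointly associated
    with a trait. Gene-level P-values are computed by an exact circular
    genomic permutation correction of the best-SNP statistic (fastCGP),
    converted to z-scores and overlaid on the PPI; score-dense modules are
    grown from every seed gene, collapsed by Dice similarity, matched
    across two parallel datasets, and the consensus module is assessed by
    circular-permutation, topology-free, connected-random-module
    (Metropolis-Hastings random walk), hypergeometric and connectivity
    permutation tests. Includes a synthetic-data generator producing
    parallel GWAS datasets with linkage-disequilibrium-blocked P-values, a
    scale-free PPI and a planted high-score module for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, NetworkEnrichment, GraphAndNetwork,
    Software
RoxygenNote: 7.3.3
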