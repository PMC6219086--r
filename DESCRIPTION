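Package: regulonet
Title: Synchronous Multi-Network Selection and Bacterial Regulatory Motif
    Exploration
Version: 0.1.0
Authors@R:
    person("Regulonet", "Maintainers", email = "maintainers@regulonet.example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for comparative network biology and bacterial
    regulatory genomics. Imports interaction networks (SIF, XGMML, zipped
    session archives) into a shared node-identity space, propagates node
    selections across networks through user-supplied homolog maps, and
    computes per-node differential topology (degree, clustering coefficient,
    connected components, exclusive edges). A second tool chain takes a gene
    selection from such a network, extracts upstream promoter regions from a
    GenBank genome, discovers motifs under a zero-or-one-occurrence-per-
    sequence (ZOOPS) EM model, scans the whole genome with the resulting
    position weight matrices against an order-3 Markov background, rejects
    genic occurrences, aggregates intergenic hits per downstream gene, and
    iteratively expands the putative regulon to convergence. Deterministic
    synthetic-data generators (planted-motif genomes, homologous network
    pairs) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    xml2,
    jsonlite,
    optparse,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
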