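Package: screp
Title: Single-Cell Immune Repertoire Analysis and Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("screp", "developers", email = "screp@example.org", role = c("aut", "cre"))
Description: Parses 10x-cellranger-style single-cell V(D)J output for B- and
    T-cell receptors, assembles paired-chain cell records, groups cells into
    clonotypes under several strategies (CDR3 nucleotide or amino-acid
    identity, germline V/J gene usage, CDR3 length gating, and CDR3 homology
    clustering), and computes repertoire statistics: clonal expansion ranking,
    isotype composition per clone, CDR3 length distributions, position
    probability matrices for sequence logos, V-J pairing counts, and diversity
    indices. Quantifies somatic hypermutation as alignment mismatches against
    extracted germline references, builds germline-rooted neighbor-joining
    clone trees with identical-sequence collapsing, and constructs clone
    similarity networks from summed per-chain CDR3 edit distances. Integrates
    V(D)J clonotypes with gene-expression data: mitochondrial filtering,
    receptor-gene removal, graph-based clustering, barcode matching, cluster
    membership per clone, marker-based phenotype labels, expanded-versus-
    unexpanded differential expression, hypergeometric gene-set enrichment,
    and preranked GSEA. Ships deterministic simulators of cellranger-style
    V(D)J tables and expression matrices with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
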