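Package: pairid
Title: Pairwise-Alignment Identity Matrices for Sequence Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes genetic identity for every unique pair of nucleotide or
    amino-acid sequences by independent global (Needleman-Wunsch) alignment
    with affine gap penalties, scoring each pair as the fraction of identical
    residues among alignment columns where neither sequence has a gap. The
    all-pairs identity matrix is ordered by a neighbour-joining tree so that
    related sequences cluster together, and can be rendered as a colour-coded
    matrix or summarised as an identity-frequency distribution to support
    identity-threshold based taxonomic demarcation (for example ICTV virus
    species criteria). Completed analyses can be saved as sessions, extended
    incrementally with new sequences, and partitioned into non-overlapping
    FASTA files by identity range.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    tools,
    utils,
    stats,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
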