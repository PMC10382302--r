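Package: chromcooc
Title: Transcription Factor Co-Occurrence in 3D Chromatin Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor pairs that co-occur significantly more
    ("attraction") or less ("repulsion") than expected by chance across spatially
    proximal and sequentially contiguous chromatin regions. Builds a region-region
    interaction network from chromatin-contact anchor pairs (ChIA-PET, Hi-C), maps
    ChIP-seq peaks or motif occurrences onto it as a bipartite binding network, and
    assesses pairwise co-occurrence against a degree-class-preserving network
    randomization with empirical two-tailed p-values and Benjamini-Hochberg q-values.
    Includes position-weight-matrix utilities (information content, log-likelihood-
    ratio scanning with exact score-distribution p-values), downstream enrichment
    statistics (hypergeometric 2x2 tests, target-gene assignment, TSS-distance
    distributions, shortest-PPI-path internal nodes), consensus network construction,
    and a synthetic-data generator with planted attraction/repulsion structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
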