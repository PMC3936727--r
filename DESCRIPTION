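Package: crispam
Title: PAM Discovery from CRISPR Spacer-Protospacer Matching and Cas9
    Ortholog Grouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers protospacer adjacent motifs (PAMs) for type II
    CRISPR-Cas systems by matching CRISPR spacers against candidate
    target sequences at a configurable identity threshold, extracting
    the 10-nt flank immediately 3' of each protospacer on the
    non-target strand, and summarising the flanks as a position
    frequency matrix, per-position information content (sequence-logo
    data) and a degenerate IUPAC consensus.  Also provides the
    companion comparative-genomics computations: all-vs-all protein
    alignment and greedy single-linkage clustering of Cas9 orthologs
    under length-coverage and score-coverage thresholds, a
    distance-based neighbor-joining grouping with column bootstrap and
    monophyly checks, a simplified repeat:anti-repeat RNA
    hybridization scorer, and a fully reproducible synthetic-data
    generator that plants protospacers with a known ground-truth PAM
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    ape,
    igraph,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
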