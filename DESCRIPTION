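Package: gliadinkit
Title: Alpha-Gliadin Locus Analysis: Pseudogene Classification, Epitope
    Scanning, Phylogeny and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing alpha-gliadin (Gli-2 locus) gene families
    in wheat and its wild relatives. Provides gene anatomy and
    poly-glutamine domain segmentation, mutation-event detection and
    intact-versus-pseudogene classification with stop-codon context
    analysis (the C-to-T glutamine-codon to stop-codon transition),
    celiac-disease T-cell epitope scanning with 33-mer-like cluster
    detection, neighbor-joining phylogeny with bootstrap support,
    stringent-identity read assignment with FPKM quantification, locus
    summary statistics and shared transposable-element orthology
    inference, plus a fully deterministic synthetic-locus simulator so
    that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
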