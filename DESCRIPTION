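Package: opsinteny
Title: Synteny-Anchored Reconstruction of Visual Opsin Duplication History
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the duplication history of the
    vertebrate visual opsin gene family from gene arrangements rather than
    sequence phylogeny alone. Provides a synthetic-genome simulator with
    explicit whole-genome duplication (1R, 2R) and cyclostome triplication
    events and a truth ledger; detection of same-chromosome, same-strand
    opsin subtype pairs split at a proximal/distal distance boundary;
    distance-based opsin subtype classification with bootstrap support;
    selection of synteny anchor gene families; chromosome-keyed supermatrix
    construction with neighbor-joining bootstrap trees and outgroup rooting;
    and an exact event-parsimony engine that ranks alternative pre-1R
    ancestral gene arrangements by the number of tandem duplications,
    losses, and translocations they require.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
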