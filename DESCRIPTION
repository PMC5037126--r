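Package: fadssn
Title: Sequence Similarity Networks for Membrane Fatty Acid Desaturase
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sequence similarity networks (SSNs) over protein
    superfamilies and uses them to classify membrane-bound fatty acid
    desaturases into families and subfamilies by lipid head-group
    specificity.  Provides exact Smith-Waterman local alignment with
    Karlin-Altschul E-value calibration, greedy collapse of near-identical
    sequences into representative nodes, logE-threshold filtration of the
    network with connected-component clustering, annotation overlay and
    consensus substrate calls, nearest-representative classification of
    query sequences, a distance-based neighbor-joining companion tree, and
    a synthetic superfamily generator with planted family/subfamily
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
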