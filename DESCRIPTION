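Package: matsite
Title: Prediction of Mature miRNA Processing Sites in pre-miRNA Hairpins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts all four mature-miRNA processing sites (5' arm
    start/end, 3' arm start/end) within a pre-miRNA hairpin. Builds a
    gapped two-strand duplex alignment of the hairpin stem (the
    "structured sequence", in which '-' marks nucleotides left unpaired
    by bulges and internal loops), slides 22-nt candidate windows along
    each arm, extracts structure-aware feature vectors, ranks features
    by information gain, chi-square and Relief, rebalances the candidate
    classes by K-means centroid-proximity undersampling, and trains an
    AdaBoost ensemble of probability-output RBF-kernel support vector
    machines. Includes position-deviation evaluation metrics and a
    seeded synthetic-hairpin generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
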