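Package: sseforest
Title: Template-Based SCOP Classification of Protein Domains from
    Secondary-Structure-Element Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents a pair of protein domains with an equal number of
    secondary structure elements (SSEs) by geometric descriptors of those
    elements (centroid distances, inter-axis angles, solvent accessibility,
    length, SSE type) plus descriptor root-mean-square differences and
    sequence identity, and predicts the deepest SCOP level the two domains
    share (Class, Fold, Super-family, Family, or none) with a bagged random
    forest whose per-class probabilities are leaf class-ratio averages over
    trees. Includes readers for PDB coordinates, DSSP output and ASTRAL
    dir.cla classification files, the probability decision rules for
    proposing classifications of unassigned domains, multi-class evaluation
    metrics (precision, recall, Matthews correlation coefficient), and a
    synthetic hierarchy generator for end-to-end validation without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
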