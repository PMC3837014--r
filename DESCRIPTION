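Package: solenoidscan
Title: Neural-Network Detection of Alpha-Solenoid Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects alpha-solenoid repeat domains (HEAT, Armadillo, TPR,
    ankyrin and related folds) in protein sequences without relying on
    sequence homology. A small multilayer perceptron scores every residue
    of a query sequence as a candidate repeat-linker midpoint from a
    39-position one-hot sequence window; variable helix-helix linkers of
    one to three residues are handled by testing four window-shift
    combinations per position and keeping the maximum score. Proteins are
    classified as alpha-solenoids when three or more high-scoring hits
    chain with the 30-135 residue periodicity characteristic of stacked
    helical repeats. Includes supervised back-propagation training from
    annotated corpora, a synthetic sequence generator with known linker
    annotations for training and benchmarking, precision-recall threshold
    sweeps with operating-point selection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
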