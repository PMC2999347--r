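Package: sirnaforest
Title: Random-Forest Feature Selection and Support Vector Classification
    of siRNA Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts short interfering RNA (siRNA) potency from the 19-nt
    antisense guide sequence. Encodes each sequence as 120 features in six
    groups (positional nucleotide codes, mono-, di- and trinucleotide
    frequencies, global and local G/C content, and secondary-structure
    minimum free energy via a pluggable folding backend), selects
    informative features by out-of-bag permutation importance across an
    ensemble of random forests grown over a grid of node-sampling sizes,
    and classifies potent versus non-potent siRNAs with a radial-basis
    -kernel support vector machine. Includes stratified fivefold
    cross-validation with pooled accuracy, sensitivity, specificity,
    Matthews correlation and ROC/AUC, a correlation analysis of classifier
    output against knockdown efficacy, and a seeded synthetic-data
    generator with planted motif effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
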