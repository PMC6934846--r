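Package: kmotif
Title: Grammar-Based Motif Discovery for Open-Field Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies free movement of animals in an open-field arena by
    mining frequent symbolic motifs from position recordings. Trajectories are
    reparameterised into spatial relations (absolute and relative position,
    distance to the nearest object and to the arena boundary), discretized with
    Symbolic Aggregate Approximation (SAX), and compressed with the Sequitur
    grammar-induction algorithm; recurring grammar rules are ranked by
    interestingness measures combining frequency, length and diversity, and the
    top-ranked motifs per experimental group become count-based feature vectors
    for classification. Includes stratified cross-validated evaluation with
    four standard classifiers, weighted-F1 scoring, hill-climbing
    hyperparameter search, baseline feature methods, and a synthetic cohort
    generator emulating exploratory versus repetitive object-checking
    behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    class,
    e1071,
    nnet,
    rpart,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
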