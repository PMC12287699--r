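Package: selcnn
Title: Detecting Interspecific Positive Selection in Codon Alignments with
    Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates protein-coding sequence evolution under site-class
    dN/dS codon models with insertions and deletions along a symmetric
    phylogeny, tracking the true alignment; encodes alignments as one-hot
    tensors; trains a codon-aware convolutional neural network to classify
    genes as evolving with or without positive selection; evaluates the
    classifier with ROC and precision-recall metrics; and interprets
    predictions with gradient saliency maps over alignment positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
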