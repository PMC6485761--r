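Package: mmcnn
Title: Multi-Modal Multi-Sized-Filter Convolutional Networks for RBP Binding Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-binding-protein (RBP) binding sites from RNA sequence and
    secondary-structure ensembles with a bimodal convolutional neural network that
    uses parallel filters of several lengths (the mmCNN architecture). Suboptimal
    secondary structures with free energies are converted into a Boltzmann-weighted
    stem-pair probability matrix that serves as the structure input channel.
    A response-enrichment procedure extracts aligned sequence, structure, and
    combined binding motifs from the trained filters, exported as MEME-format
    position weight matrices. A synthetic planted-motif data generator with full
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    pROC,
    Biostrings,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
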