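Package: gocapgan
Title: Capsule-Network Wasserstein GAN for Protein Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of GOCAPGAN: a Wasserstein GAN with
    gradient penalty over protein sequences whose critic ends in a capsule
    layer with dynamic routing, followed by transfer-learning feature
    extraction from the trained critic and a multi-label Gene Ontology
    classifier evaluated by repeated k-fold cross validation. Includes a
    synthetic proteome generator that plants k-mer motifs as learnable
    sequence-to-function signal, FASTA/TSV ingestion, capsule-network
    primitives (squash, affine votes, routing by agreement), and the
    paper-standard multi-label metrics (precision, recall, F1, Hamming
    loss). All networks are trained on a small tape-based reverse-mode
    automatic-differentiation engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
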