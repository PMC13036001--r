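Package: lcgen
Title: Heavy-Chain-Conditioned Generation of Antibody Light-Chain Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and runs an encoder-decoder next-token model that generates
    antibody light-chain variable-domain (VL) sequences conditioned on a heavy
    chain (VH), with constrained decoding (germline seeding, CDR grafting on
    conserved cysteine/tryptophan/phenylalanine anchors), likelihood and
    perplexity scoring, a native-versus-germline-reverted pairing-preference
    statistic, post-generation filtering with evenly spaced diversity
    selection, and repertoire-level evaluation metrics (germline assignment,
    per-region mutation counts, heavy/light co-evolution correlation). A
    desk-scale synthetic paired-repertoire generator with germline ground
    truth provides training data and test oracles end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
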