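Package: chromTU
Title: Transcription Unit Calling from Histone Modification ChIP-seq with a
    Semi-Supervised Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls active transcription units (TUs) genome-wide from binarized
    ChIP-seq enrichment of the six IHEC class 1 histone modifications. Implements
    a 17-state multivariate Bernoulli-emission hidden Markov model with a
    duplicated forward/reverse TU chain and three background states, constrained
    Baum-Welch training with clamped (supervised) parameters and structural-zero
    transitions, Viterbi decoding into strand-assigned TU records, binomial
    mixture enrichment calling of ChIP over control counts at a target FDR,
    supervised parameter estimation from a transcript annotation with an RNA
    polymerase II training filter, bin-level ROC/PRC evaluation against a nascent
    RNA plus Pol II gold standard including a subsampled AUC estimator for
    class-imbalanced genomes, and seeded synthetic-data generators for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
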