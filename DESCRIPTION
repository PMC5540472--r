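Package: caresig
Title: Multimodal Help-Requirement Recognition from Skeleton and EEG Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognises the help requirement of mobility- and vocality-limited
    care-home patients from two synchronised signal streams: depth-camera
    skeleton trajectories (20 joints) and 8-channel EEG. Implements the full
    pipeline: a synthetic generator for labelled skeleton+EEG records,
    200-dimensional motion and 80-dimensional mental (band-power) feature
    extraction, stacked sparse autoencoders with a KL-divergence sparsity
    penalty trained by greedy layer-wise pretraining and supervised softmax
    fine-tuning, single-modal / early-fusion / late-fusion architectures, a
    dynamic-time-warping 1-nearest-neighbour baseline, and a shuffled or
    continuous (sliding-frame) cross-validated evaluation protocol reporting
    accuracy, macro recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
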