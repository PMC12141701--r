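Package: soxfe
Title: Self-Organized Explainable Feature Engineering for Two-Class EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a self-organized explainable feature-engineering (SOXFE)
    pipeline for two-class multichannel EEG classification. Features are
    extracted per sample with a channel-pair distance-matrix pattern (DMPat)
    encoder whose min/max pair codes are histogrammed; an iterative
    neighborhood-component-analysis (INCA) selector picks the loss-minimizing
    top-r feature subset; an ensemble k-nearest-neighbour classifier (tkNN)
    enumerates a distance-weight-k grid, adds iterative majority voting and
    keeps the most accurate outcome; branch predictions are fused by the mode
    operator. Selected feature indices are decoded into Directed Lobish (DLob)
    brain-lobe symbol strings with histograms, Shannon entropies and cortical
    connectome transition graphs. Includes readers for EDF, delimited-text and
    MATLAB v7.3 signal matrices, a synthetic EEG data generator with planted
    channel-pair structure, stratified tenfold and leave-one-record-out
    cross-validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
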