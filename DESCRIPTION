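Package: psolstm
Title: Attention-Based LSTM with Particle Swarm Hyperparameter Search for
    EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-dependent emotion classification from multichannel EEG.
    Implements baseline-relative time-domain feature extraction (3-second
    segmentation, baseline subtraction, per-channel standardization and
    valence/arousal quadrant labelling), a two-layer LSTM classifier with an
    additive attention mechanism over the hidden-state sequence, and a
    particle swarm search over five model hyperparameters (LSTM units, dense
    units, dropout rate, batch size). Includes readers for the DEAP and SEED
    per-subject array layouts, a class-conditional synthetic EEG generator so
    the full pipeline is testable without restricted datasets, per-subject
    experiment drivers with attention and fixed-hyperparameter ablations, and
    result aggregation across subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
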