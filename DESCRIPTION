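Package: microstates
Title: Probabilistic EEG Microstate Segmentation and Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end probabilistic analysis of EEG microstates. Extracts
    scalp topographies at global field power (GFP) peaks, clusters them with
    hard K-means (kmeans++) and fuzzy C-means, merges polarity-inverted
    duplicate template maps, trains a softmax multilayer perceptron on the
    cluster assignments, and assigns a probability distribution over
    microstates to every EEG timepoint. Includes uncertainty analyses
    (ECDF of the maximum-likelihood-label probability, subject-level
    GFP-versus-certainty regression), a synthetic EEG generator with known
    ground-truth state sequences, minimal EDF/EDF+ input-output, and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    cluster,
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
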