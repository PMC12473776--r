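Package: incnn
Title: Interpretable Convolutional Feature Extraction for Multivariate Time
    Series with Pairwise Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements InCNN, a convolutional feature extractor for
    multivariate time-series classification whose parallel, zero-masked
    filter banks produce a flattened feature vector with one contiguous
    block per input variable and per pairwise variable interaction.
    Features are extracted after a two-phase (pre-train/fine-tune)
    training schedule and fed to an impurity-based tree ensemble, yielding
    quantified importance scores for individual variables and variable
    pairs alongside competitive classification accuracy. Includes sliding
    window segmentation, no-interaction and 1D-convolution baseline
    architectures, a synthetic pairwise-interaction data generator, and
    experiment harnesses with a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
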