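Package: rtdecoder
Title: Decoding Speech Categorization Speed from EEG Spatial-Spectral Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end framework for decoding behavioral response-speed
    categories (fast, medium, slow) from epoched multi-channel EEG.
    Response times are partitioned with Gaussian mixture models selected by
    BIC; event-related potentials are augmented by controlled bootstrap
    averaging with category-specific trial dropout and filtered by PCA
    reconstruction error; alpha/beta/gamma bandpowers are rendered as
    RGB-stacked scalp topomap images; a configurable convolutional network
    classifies the maps, with a tree-structured Parzen estimator for
    hyperparameter search; Guided-GradCAM saliency maps are quantified per
    electrode and frequency band and analysed with factorial mixed-model
    ANOVA, Tukey posthoc contrasts and GMM-based activation ranking.
    A synthetic-data generator with planted spatial-spectral effects makes
    the whole chain testable without access to recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nnet,
    withr
Config/testthat/edition: 3
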