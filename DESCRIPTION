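Package: dvpclust
Title: Unsupervised Clustering of Digital Volume Pulse Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised shape analysis of photoplethysmogram (PPG) digital
    volume pulses (DVPs). Provides a synthetic-data generator planting the four
    classic notch-based pulse morphology classes with age-coupled clinical
    covariates, pulse normalization, fourteen handcrafted morphology features,
    banded derivative dynamic time warping (DDTW) dissimilarities, a 1-D
    convolutional autoencoder feature extractor, K-medoids (PAM) clustering with
    free, template-fixed and model-selected medoids, cluster-number selection by
    silhouette, inertia and prediction strength, and a weighted
    quantile-function distance scoring how well clusters separate clinical
    covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
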