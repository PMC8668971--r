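Package: voccSpectra
Title: Cross Correlation-Periodogram Analysis of Tumor Slice Texture
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies across-slice texture consistency of tumor regions of
    interest in multi-slice grayscale imaging (e.g. structural MRI of low-grade
    glioma) and uses it to predict 1p/19q co-deletion status. Implements the
    variance of cross-correlation (VoCC) statistic over full-lag 2D
    cross-correlation of consecutive masked slices, Lomb-Scargle power spectral
    density estimation of VoCC curves with first-peak exclusion, three spectral
    classification features (difference energy, total volumetric energy,
    cut-off frequency), and a RUSBoost ensemble classifier with stratified
    k-fold evaluation. Includes a synthetic phantom generator producing
    labeled 3-slice stacks with controlled across-slice texture consistency,
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, rpart, png
Suggests: testthat (>= 3.0.0), jsonlite, optparse, RNifti, withr, knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
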