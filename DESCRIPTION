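Package: plaquesync
Title: Motion-Synchronisation Analysis of Carotid Plaque from B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies synchronisation patterns of carotid atheromatous
    plaque motion from B-mode ultrasound image sequences. Tracks annotated
    wall and plaque interfaces with adaptive block matching and Kalman
    smoothing, builds radial and longitudinal displacement waveforms,
    estimates phase shifts between tissue regions by normalised
    cross-correlation, computes plaque echogenicity (grayscale median after
    blood/adventitia normalisation), and associates the resulting
    24-feature synchronisation signature with plaque phenotypes via PCA,
    adaptive synthetic oversampling, Random Forests under leave-one-out
    cross-validation, and Wilcoxon rank-sum tests. Includes a synthetic
    speckle-phantom generator with known ground-truth motion so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
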