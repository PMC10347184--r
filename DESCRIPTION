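Package: stresswear
Title: Stress Classification from Multimodal Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and deep-model evaluation pipeline for
    three-class stress detection from wearable photoplethysmography (PPG),
    electrocardiography (ECG) and electroencephalography (EEG) recordings.
    Provides a synthetic cohort generator with stress-dependent cardiac and
    cortical structure, a fixed-grid resampling / Butterworth band-pass /
    sliding-window preprocessing chain, self-supervised signal-transformation
    pretext tasks, three 1-D deep architectures (a multi-kernel residual
    network, a convolutional-recurrent network and a self-supervised
    convolutional encoder) trained with Adam, and stratified k-fold
    evaluation with per-class metrics, averaged confusion matrices and
    breakdowns by signal combination, scenario and task difficulty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
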