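Package: cytofuse
Title: Multimodal Optical and Impedance Cytometry Particle Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multimodal microfluidic particle
    characterization combining high-speed-camera imaging with multi-frequency
    impedance cytometry. Provides a synthetic acquisition simulator
    (co-registered frame stacks, impedance traces and ground truth), optical
    particle sizing via rolling-background subtraction and radial intensity
    profiling, impedance peak extraction with baseline normalization,
    time-based event fusion, volume-impedance regression validation, and
    decision-tree classification with stratified cross-validation and a full
    confusion-matrix metric suite (accuracy, sensitivity, specificity,
    fallout, false-negative rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
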