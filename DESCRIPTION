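Package: sacdec
Title: Trans-Saccadic Spatial-Frequency Decoding of Multichannel Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-resolved decoding of
    visual spatial frequency across saccadic eye movements from multichannel
    (MEG-style planar gradiometer) recordings. Provides a ground-truth
    synthetic-data generator for a factorial saccade/fixation change-detection
    design, velocity-threshold saccade detection, photodiode event extraction,
    epoch cutting with rule-based exclusion, event-related planar-gradient
    averages, cross-validated and cross-condition temporal-generalization
    classification with a temporal searchlight, diagonal-band readouts,
    empirical-logit conversion, and group-level sign-flip permutation tests
    with threshold-free cluster enhancement over sensor-by-time maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
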