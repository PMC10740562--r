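Package: aptasignal
Title: Deep-Learning Analysis of Electrochemical Aptasensor Drain-Current Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and deep-learning analysis of
    drain-current time series recorded by aptamer-functionalized
    carbon-nanotube field-effect-transistor (CNT-FET) biosensors.
    Provides a synthetic-signal generator that emulates staircase sensing
    responses to rising analyte concentrations together with three anomaly
    archetypes; z-score normalization, segmentation, resampling and
    short-time Fourier transform (Blackman window) spectrogram features;
    conditional and unconditional variational autoencoders for segment
    augmentation; recurrent (GRU/LSTM) sliding-window signal extrapolation;
    and seven recurrent, convolutional-recurrent and convolutional
    classifier architectures for analyte identification, quantification and
    anomaly discrimination, evaluated by confusion-matrix metrics. All
    neural-network layers, losses and the Adam optimizer are implemented in
    base R linear algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
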