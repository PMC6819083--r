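Package: photoflux
Title: Fiber Photometry Signal Processing and Quantification
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-channel (490/405 nm) fiber
    photometry: lock-in demodulation of amplitude-modulated raw signals,
    zero-phase Butterworth filtering and decimation, isosbestic reference
    fitting and dF/F computation, robust z-score normalization, prominence
    based transient detection with FWHM measurement, peri-event trial
    alignment and feature extraction (CS/US peaks, anti-peak, rebound AUC),
    lick-bout and freezing behavioral metrics, SWC-based neuron morphometry
    (Sholl profiles, neurite length, soma shape), and the group statistics
    layer used in photometry studies (summary-based t tests, two-sample
    Kolmogorov-Smirnov, Bonferroni and Benjamini-Krieger-Yekutieli two-stage
    FDR). Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without recordings.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
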