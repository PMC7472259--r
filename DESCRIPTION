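Package: pulsefusion
Title: Sensor-Fusion Detection of the TCM Wiry Pulse from PPG and
    Acupoint Skin-Impedance Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for traditional-Chinese-medicine (TCM) pulse-type
    screening from low-cost wearable sensors. Provides synthetic generators for
    quasi-periodic photoplethysmography (PPG) recordings and 24-channel
    galvanic-skin-response (GSR) acupoint panels; periodic moving-average
    denoising and sliding-window segmentation; event-related moving-average
    delineation of per-beat fiducial points (pulse onset, systolic peak,
    diastolic peak); eight time-domain and ten harmonic (resonance-theory)
    waveform features; median-based acupoint panel reduction with bilateral
    symmetry diagnostics; and a fully connected neural-network classifier with
    subject-level stratified cross-validation, modality-ablation tables, and
    random-forest feature importance with group statistics. All results are
    tibbles; fitted objects have tidy(), glance(), and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
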