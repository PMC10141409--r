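Package: ferrotrace
Title: Analysis of Single-Molecule Plasmonic Trapping Transmission Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing optical-transmission time traces from
    plasmonic nanotweezer (double-nanohole) trapping experiments on
    ferritin: Gaussian low-pass filtering, decimation and mode
    normalization; trapping/release step detection and dielectric-loading
    (deltaT/T0) estimation; sliding-RMS, NRMS, kernel-density and spectral
    band-fraction fluctuation metrics; two-state on/off segmentation of
    iron-loading gating with dwell-time kinetics and mineralization
    trends; and seeded permutation tests for apo- vs holo-ferritin
    comparison. Includes a physics-based synthetic trace generator
    (Clausius-Mossotti polarizability, exact-discretization
    Ornstein-Uhlenbeck trap dynamics, band-limited conformational noise,
    two-state Markov gating) with ground-truth channels so every analysis
    stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
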