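Package: tistim
Title: Modeling, Optimization and Visualization of Temporal Interference Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling interferential (temporal interference) transcranial
    electric stimulation. Builds synthetic lead fields on concentric-sphere volume
    conductors with a finite-difference Laplace solver, superposes two-frequency
    stimulation fields, extracts amplitude-modulation envelopes via the analytic
    signal, computes static and instantaneous modulation depth along arbitrary
    direction fields, optimizes two-pair and multi-electrode-array montages for
    focal deep targets, and renders the field dynamics (Lissajous traces, slice
    maps, frame-by-frame animations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
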