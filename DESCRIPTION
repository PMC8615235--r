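Package: ncscts
Title: Nerve Conduction Waveform Features and Automatic Carpal Tunnel
    Syndrome Electrodiagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the automatic electrodiagnosis of carpal tunnel
    syndrome from nerve conduction study (NCS) waveforms. Provides a
    seeded generator of grade-conditional synthetic sensory and motor
    evoked potentials, moving-average smoothing and baseline detrending,
    slope-based detection of the onset/peak/trough/offset critical
    points, extraction of 34 geometric waveform features per trace
    (amplitudes, latencies, conduction velocities, areas and their
    half-maximum subarea partition, durations, secant and regression
    slopes) assembled into a 302-entry per-hand vector with median-ulnar
    difference features, a Bland-modified four-grade severity rule,
    a custom two-phase backward/forward wrapper feature selection, and
    leave-one-out cross-validated evaluation of five classifiers with
    confusion-matrix reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    nnet,
    pracma,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
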