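Package: spindleloc
Title: Multichannel Sleep Spindle Detection and Cross-Modality Event Analysis
Version: 0.1.0
Authors@R:
    person("Dana", "Voss", email = "dana.voss@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles in multichannel electrophysiological
    recordings (sensor- or source-space EEG/MEG) with a thresholded complex
    Morlet wavelet detector, aggregates per-channel detections into discrete
    cross-channel spindle events with spatial extent and density, and
    quantifies concordance between detection modalities (temporal-overlap
    precision/recall/F1, extent correlation, false-positive topography and
    sigma-power validation) as well as test-retest reliability of event
    density via variance-component intraclass correlation with bootstrap
    confidence intervals. Includes EDF and raw-container I/O, hypnogram
    handling with N2 epoch extraction, SVD-based sign-consistent averaging of
    source-label time courses, and a synthetic-data generator producing
    nap-like 1/f recordings with ground-truth spindle bursts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
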