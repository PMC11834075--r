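Package: swrlamina
Title: Laminar Detection and Characterization of Hippocampal Sharp-Wave Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hippocampal ripples (stratum pyramidale, 90-200 Hz) and
    sharp waves (stratum radiatum, 2-20 Hz) independently on laminar probe
    recordings under urethane anesthesia, classifies their co-occurrence into
    four event types (R, SW, SWR, cSWR), and characterizes the events by
    area-under-the-curve power laws, current-source-density and AVREC layer
    profiles, aperiodic (1/f) spectral slope and offset, and slow-oscillation
    phase. Includes PCA + k-means scoring of NonREM-like and REM-like states,
    cortical delta-wave detection, and a seeded synthetic laminar-LFP generator
    with ground-truth annotations that makes every stage testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
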