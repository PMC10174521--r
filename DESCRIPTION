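Package: dynroi
Title: Dynamic Region-of-Interest Detection of Second-Messenger Signaling
    Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated detection and characterization of second-messenger
    signaling events (calcium, cyclic AMP) in multidimensional fluorescence
    time-lapse image stacks. Pixel traces are smoothed with a temporal
    Savitzky-Golay filter and background-subtracted by their temporal
    minimum; frames are blurred and adaptively thresholded (Otsu, Yen or
    Triangle); active voxels are grouped into 4-dimensional connected
    "sites" whose per-frame cross-sections form dynamic regions of interest
    that track each signal's changing perimeter over time. Per-event
    descriptors (delta-f amplitude, duration, maximal area, origination
    site, convergence/divergence topology) are compiled into tabular and
    graphical reports. Includes synthetic ground-truth generators (noiseless
    polygonal scenario movies and Gaussian pulses embedded in Gaussian
    noise) and a signal-to-noise validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
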