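Package: pupilstate
Title: Pupillometry and Brain-State Analysis of Arousal-Dependent Thalamic Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying arousal-dependent activity in the visual
    thalamus of awake mice. Provides active-contour ("Snakuscule") pupil
    tracking from infrared eye videos, segmentation of quiet versus active
    wakefulness from the 3-6 Hz content of the cortical local field
    potential, spike-waveform cell-type classification, thalamic burst
    detection and subtyping, state-conditioned firing statistics
    (modulation index, peri-event histograms, autocorrelograms, EPSP
    rates), permutation-test correlation of firing rate with pupil
    diameter, and membrane-potential/pupil cross-correlation lag
    estimation. A synthetic-session generator with full ground truth makes
    every stage testable without external recordings, and a pipeline
    driver runs the complete analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
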