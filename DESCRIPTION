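Package: scvigor
Title: Reward Modulation of Superior Colliculus Subtypes and Saccade Vigor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-aligned superior colliculus (SC)
    recordings during value-biased visually guided saccades. Detects saccades
    from 1 kHz eye traces and computes vigor metrics (reaction time, peak
    velocity, main-sequence amplitude), estimates Gaussian-kernel spike
    density functions, classifies units into visual, visuomotor, motor and
    tonic subtypes from window firing-rate contrasts, quantifies per-unit
    reward modulation (signed-rank comparison, AUROC, modulation-onset
    latency), dissects early-visual, late-visual and pre-saccadic response
    epochs with a reaction-time-tertile pseudo-population bootstrap, and
    links value modulation to behavior through per-neuron reaction-time and
    peak-velocity correlation indices. Ships a synthetic-session generator
    (inhomogeneous-Poisson spike trains against subtype rate templates,
    minimum-jerk eye traces) with ground-truth labels so the whole pipeline
    is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
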