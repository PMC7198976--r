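Package: popspike
Title: Population Spike-Timing Analysis of Stimulus-Time Coding in Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how the timing of population spiking activity
    in sensory cortex encodes the time of a sensory stimulus or whisker touch.
    Implements pseudo-simultaneous population construction from sequentially
    recorded neurons, population-response-event (PRE) detection against a
    spikes-per-neuron threshold, the absolute stimulus-time-error statistic,
    sliding-window responsiveness and opsin-status classification, a
    subsample-plus-binomial resampling procedure with false-discovery-rate
    control, correlated spike-train simulation via a latent-Gaussian copula
    with exact peri-stimulus rate profiles, touch-stream and membrane-potential
    sweep generators, and intracellular response metrics (state classification,
    evoked-response peaks and areas, synaptic charge, intrinsic properties).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
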