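Package: predgain
Title: Expectation and Adaptation Effects on Orientation Coding in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how stimulus
    predictability modulates orientation-selective responses in primary
    visual cortex. Generates random and rotating grating sequences with
    labelled expectation violations, simulates calcium-imaging (dF/F)
    population recordings with an injected gain enhancement for unexpected
    stimuli, fits circular Gaussian tuning curves, decodes orientation from
    population activity with a forward/inverted encoding model, runs
    sign-flip cluster permutation tests, and implements a six-channel
    gain-modulation model in which adaptation and expectation jointly
    control channel sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
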