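Package: fibrc
Title: Fiber-Memristor Physical Reservoir Computing for Multimodal Sleep Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of a fiber-memristor physical reservoir
    computing system for multimodal sleep monitoring. Encodes EEG epochs as
    Markov transition fields, snore audio as mel-frequency cepstral
    coefficients, and images as threshold pulse maps; drives a phenomenological
    diffusive-memristor model (saturating potentiation, exponential fading
    memory, power-law current readout, 16 pulse-programmable conductance
    levels) with the resulting pulse trains; and classifies the collected
    reservoir state vectors with linear softmax or lightweight convolutional
    readouts, including conductance-quantized inference, class activation
    maps, energy accounting, and a synthetic data generator for stage-labelled
    EEG, snore audio with ambient noise, hypnogram timelines, and glyph
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
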