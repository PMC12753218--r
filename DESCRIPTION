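Package: clotwave
Title: Fibrinogen Estimation from Clot Waveforms and Thrombin Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate plasma fibrinogen concentration from optical
    clot waveforms. Implements a mechanistic fibrin-polymerization model
    (enzymatic fibrinopeptide release, protofibril growth and lateral fiber
    aggregation) with a Carr-Hermans turbidity output, driven by measured or
    synthetic thrombin-generation curves, and inverts a simulated reference
    curve of maximum attenuance increase to recover fibrinogen. Also provides
    feature-based estimators (multivariate linear regression and a small tanh
    neural network trained with Adam, combined by a 6 g/L gating rule) for
    prothrombin-time and Reptilase-time turbidity waveforms, leave-one-out
    evaluation with Pearson statistics and anticoagulation strata, a seeded
    synthetic cohort generator, a clot-waveform plot digitizer, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
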