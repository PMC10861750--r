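Package: mieeg
Title: Generative Modelling and Feature Analysis of Movement-Intention EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lower-limb movement-intention EEG with a two-stage
    generative model: small neuronal assemblies modelled as van der Pol
    oscillators (primary processing, including entrainment to same-frequency
    external input) cascaded into a four-population neural mass model
    (pyramidal, excitatory, slow-inhibitory and fast-inhibitory populations
    with a fast-inhibitory self-loop). Generates trial ensembles for a
    normal and a virtual-reality induction condition, and implements the
    accompanying feature pipeline: zero-phase Butterworth filtering,
    epoching, Hanning-window STFT event-related spectral perturbation,
    event-related desynchronization onset and peak, characteristic
    frequency, movement-related cortical potential extraction, baseline
    power, paired condition comparisons and a cross-validated
    detectability score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
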