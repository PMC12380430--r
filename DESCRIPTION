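Package: odoradapt
Title: Adaptation-Invariant Odor Coding Analysis for Antennal-Lobe Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how insect antennal-lobe
    projection-neuron ensembles preserve odor identity and intensity
    information across repeated stimulus presentations while sensory
    adaptation shrinks overall response magnitude. Provides readers and
    validators for spike-event, behavior and stimulus-protocol tables; a
    seeded synthetic generator of Poisson spike trains with odor-specific
    tuning, intensity-dependent ensemble rotation, trial-wise adaptation
    under competing mechanistic models (vesicle depletion versus
    lateral-inhibition facilitation) and catch-trial designs; spike binning
    into Neuron x Time x Trial count tensors with PSTH and population-vector
    reductions; trilinear CP/PARAFAC decomposition by alternating least
    squares with the core-consistency diagnostic (CORCONDIA) for factor
    selection; population-vector geometry (trial trajectories, correlation
    matrices, complete-linkage dendrograms, leave-one-trial-out
    classification, catch-trial correlation profiles); mechanism
    discrimination regressions; and palp-opening-response behavioral
    statistics including paired one-sided tests and neural-behavioral
    regression.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
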