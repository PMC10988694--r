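Package: spindlesim
Title: Biophysical Simulation of Muscle Spindle Ia Afferent Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative biophysical model of mammalian muscle spindle
    primary (Ia) afferent encoding.  Intrafusal bag and chain fibre forces
    are simulated with a two-state cross-bridge half-sarcomere model, the
    receptor potential is generated as a weighted sum of half-wave
    rectified force and yank, and spiking is produced by a multicompartment
    cable model of the Ia terminal arbor, preterminal axon, heminode and
    myelinated nodes of Ranvier carrying an asymmetric constellation of
    voltage-gated channels (Nav1.1, Nav1.6, Nav1.7 Markov gating models
    with slow inactivation; Kv1, Kv3.3, KCNQ Hodgkin-Huxley models; a
    calcium-dependent SK2 conductance).  Includes spike-train feature
    extraction (initial burst, peak dynamic rate, static rate), model
    calibration, and morphology and conductance perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
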