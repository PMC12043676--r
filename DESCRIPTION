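Package: tensdepth
Title: Pulse-Width Dosimetry for Transcutaneous Electrical Nerve Stimulation
Version: 0.1.0
Authors@R: person("tensdepth", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Desk-scale computational dosimetry for transcutaneous electrical
    nerve stimulation (TENS) on a layered forearm phantom. Solves the Ohmic
    quasi-static volume-conductor problem on a voxel grid with surface gel
    electrodes, drives a double-cable myelinated sensory axon model with the
    sampled extracellular potentials, titrates excitation thresholds across
    pulse widths to build strength-duration curves (rheobase, chronaxie), and
    estimates the volume of tissue activated from Hessian-eigenvalue
    activating-function maps, including the activation-depth versus
    pulse-width relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
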