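Package: enerdiss
Title: Energy Dissipation Modelling of Perturbation Propagation in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the dissipation of a kinetic-energy perturbation
    through a coarse-grained (C-alpha elastic network) protein model and
    characterizes the process with the energy-dissipation-model machinery:
    per-residue response times from paired perturbed/reference
    microcanonical trajectories, the cumulative dissipation curve NR(t),
    two-state Boltzmann fits yielding the half response time and the
    dissipation rate constant, Lorentzian fits of variant-versus-wild-type
    difference curves, and residue dynamical-module partitions
    cross-tabulated against structural regions.  Includes deterministic
    synthetic-fixture generators and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
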