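Package: fabsense
Title: Simulation and Analysis of Fabric-Mounted Inertial Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based simulation of a pendulum-and-fabric test rig with
    virtual single-axis accelerometers, together with the statistical machinery
    used to study whether motion artefacts from loosely attached (fabric-mounted)
    sensors help discriminate similar motions. Provides a compound-pendulum and
    serial-chain fabric dynamics simulator producing seeded, reproducible trial
    datasets; cluster-model similarity scoring (Euclidean distance, min-max
    normalization, one-way ANOVA group comparisons); an online sliding-window
    kernel classification protocol with cross-validated hyperparameters and
    leave-one-out repeats; and configuration-driven experiment scenarios with
    CSV/JSON artifacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
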