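Package: kinetrax
Title: Simulation and Analysis of Single-Molecule Kinesin Motility on
    Microtubule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse single-molecule motility of
    processive, track-switching kinesins on two-dimensional microtubule
    networks. Provides a stochastic state-machine trajectory generator with
    stepwise photobleaching and kymograph rendering; segmentation of motor
    tracks into processive, diffusive, paused and end-dwelling states;
    run-length, residency, pause and velocity statistics with bootstrap
    standard errors of the median; four-way classification of motor behaviour
    at microtubule intersections (pass, switch, pause, dissociate); optical
    trap bead-trace simulation with detachment-load detection;
    change-point counting of photobleaching steps; and Poisson bead-binding
    statistics together with hyperbolic microtubule co-sedimentation
    affinity fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
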