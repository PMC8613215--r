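Package: vhisim
Title: Active-Inference Simulation and Force Analysis for the Virtual Hand Illusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the involuntary lateral forces produced during the
    virtual (rubber) hand illusion with an active-inference model of a
    one-degree-of-freedom arm. Perception, action, sensory precision and the
    visuo-tactile causal belief evolve jointly by prediction-error
    minimization in generalized coordinates. Includes a visuo-tactile
    event-train generator mapping stimulation synchrony to the causality
    weight kappa, a virtual-cohort simulator with participant-level
    variability, the block/trial schedule of the human experiment, and the
    force preprocessing and repeated-measures statistics pipeline applicable
    to simulated or recorded trial tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
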