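Package: emdtrigger
Title: Simulation and Analysis of EMG-Triggered Robotic Arm Assistance
    Within the Electromechanical Delay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse closed-loop experiments in which a
    tethered actuator assists or perturbs rapid arm extension within the
    electromechanical delay between muscle activation and contraction.
    Includes the adaptive rest-period onset detector (threshold 1% above the
    previous rest-period maximum squared EMG), a synthetic cohort generator
    that emulates cue-driven trials with agonist/antagonist surface EMG and
    wrist/elbow marker kinematics, the EMG envelope and per-trial outcome
    pipeline (normalized activation peaks, peak arm angular velocity,
    reaction time), and linear mixed-model condition contrasts with
    Bonferroni-Holm adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    emmeans,
    jsonlite,
    lme4,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
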