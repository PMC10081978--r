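Package: coordphase
Title: Bimanual Coordination Dynamics and Continuous Relative Phase Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of rhythmic bimanual coordination under
    viscous and elastic force-field loading. Implements the extended
    Haken-Kelso-Bunz (HKB) relative-phase potential with detuning, stochastic
    (Langevin) phase simulation, synthesis of robot-exoskeleton-style
    two-hand kinematic trials, Hilbert-transform continuous relative phase
    (CRP) with per-trial stability and variability summaries, and linear
    mixed-effects comparison of load conditions with Tukey-adjusted
    estimated-marginal-means contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
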