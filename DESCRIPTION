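Package: tmrstruct
Title: Simulation and Analysis of Targeted Memory Reactivation Structure-Transfer Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing category structure-learning
    experiments with sleep-based targeted memory reactivation (TMR).
    Provides graph-structured category generators (modular and ring-lattice
    feature-covariation graphs), missing-feature training-task construction,
    a parameterised behavioral simulator for cohort generation, structure-match
    statistics on feature-arrangement dissimilarity matrices (permutation null,
    bootstrap, nuisance-controlled regression, condition-level linear and
    logistic models), a synthetic sleep-EEG generator with hypnograms, slow
    oscillations and spindles, a simulated closed-loop slow-oscillation cueing
    engine, and cue-locked EEG analysis (Morlet time-frequency decomposition,
    ERPs, cluster-size permutation statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
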