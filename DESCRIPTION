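Package: nwrtsim
Title: Closed-Loop Simulation and Analysis of Nociceptive Withdrawal Reflex Thresholds Under Propofol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the nociceptive withdrawal reflex threshold
    (NWRt) changes with anesthetic depth. Provides a synthetic subject model
    (one-compartment propofol kinetics with an effect site, a logistic
    psychometric function, stimulus-locked EMG trace generation and an EEG
    suppression-ratio readout), an adaptive bracketing staircase controller,
    interval peak Z-score reflex detection with artifact rejection, a
    twelve-trial logistic threshold estimator, a closed-loop session runner
    reproducing a stepwise propofol dose-escalation protocol, and the
    downstream statistics: baseline averaging, normalization of each session
    into five equal time intervals, per-session linear regression slopes,
    cohort medians with interquartile ranges, and Friedman repeated-measures
    rank tests with exact permutation p-values for small panels. Session logs
    round-trip through plain CSV with a JSON sidecar so recorded sessions can
    be re-analyzed without the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
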