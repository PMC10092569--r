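Package: latetox
Title: Dose-Finding Trial Designs for Late-Onset Toxicities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation framework for phase I dose-finding trials in which
    dose-limiting toxicities (DLTs) may occur after the first treatment
    cycle.  Implements rolling-enrollment trials with partial follow-up and
    eight escalation designs: the one- and two-parameter time-to-event
    continual reassessment methods, an interval-censored survival design
    with pseudo-data priors, a proportional-odds mixed-effect (grade) design,
    a normalized total toxicity profile (nTTP) design, and three
    time-to-event interval designs (TITE-BOIN, TITE-mTPI2, rolling mTPI2)
    with isotonic final selection.  Includes enforcement and stopping rules
    (hard safety, k-fold escalation limits, sufficient information,
    posterior safety and precision stopping), a latent-variable multi-cycle
    toxicity data generator, prior calibration by geometric-mean grid
    search, and an empirical optimal benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
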