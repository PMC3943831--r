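Package: ankleloop
Title: Ankle Moment-Angle Loop Analysis of Gait Quasi-Stiffness and Work
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ankle moment-angle (hysteresis) loops during
    the stance phase of walking. Segments stance into controlled plantarflexion,
    controlled dorsiflexion and powered plantarflexion; estimates per-phase
    quasi-stiffness as the slope of the moment-angle regression; integrates
    per-phase and net loop work by the trapezoidal rule with an independent
    shoelace-area cross-check; computes joint power metrics; and aggregates
    cohorts across walking-speed conditions with repeated-measures ANOVA and
    Bonferroni-adjusted pairwise contrasts. Includes a phase-switched
    spring-damper-actuator stance generator with exact energy bookkeeping for
    validation, zero-lag Butterworth preprocessing, and delimited-text trial
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
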