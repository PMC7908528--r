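Package: fvtp
Title: Two-Point Force-Velocity Profiling of Lower-Limb Tests
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal processing and statistics for two-point force-velocity
    (F-V) profiling of the leg muscles across three functional tests:
    countermovement jumps on a force plate (impulse-momentum integration),
    maximal cycle-ergometer sprints (pedal velocity from cadence and crank
    length, force from power), and isokinetic knee extension (zero-phase
    filtering, angular-to-linear velocity conversion). Fits the linear F-V
    model from two load conditions to obtain F0, V0, the slope a = F0/V0 and
    maximal power P0 = F0*V0/4, and provides the concurrent-validity and
    generalizability statistics (Pearson correlations with Fisher-z 95%
    confidence intervals, dependent-samples t tests, Shapiro-Wilk screening).
    Includes a forward simulator that generates maximal-effort trials for all
    three tests from known ground-truth profiles so the whole pipeline is
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
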