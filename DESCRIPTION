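Package: dropletlab
Title: Scheduling, Simulation, Kinetics and Bayesian Optimization for
    Parallel Droplet Reactor Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for automated parallel droplet-reactor
    screening platforms: a collision-free scheduler for shared liquid-handler,
    flowpath and HPLC bottlenecks around a bank of parallel microreactors
    (longest-processing-time ordering with iterative shifting), a
    discrete-event simulator with reactor temperature-ramp pauses, a
    reaction-kinetics engine (rate-law integration, nonlinear rate-constant
    fitting, Eyring activation-parameter regression), a mixed
    categorical/continuous ask-tell Bayesian optimizer, and seeded virtual
    benches (SNAr kinetic profiles, a Buchwald-Hartwig response surface) so
    the whole loop runs without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
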