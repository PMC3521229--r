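Package: osmcheck
Title: Optimized Statistical Model Checking for Stochastic Pathway Models
Version: 0.1.0
Authors@R:
    person("osmcheck", "maintainers", email = "osmcheck@example.org",
           role = c("aut", "cre"))
Description: Sequential statistical model checking of probabilistic claims
    Pr{psi} >= theta about stochastic systems observed only through sampled
    Boolean outcomes. Implements Wald's sequential probability ratio test with
    an indifference region, the two-acceptance-test procedure with an
    undecided-rate bound, and two optimized algorithms that remove the
    user-chosen indifference region by starting at the widest half-width and
    halving it on undecided outcomes while reusing all previously drawn
    samples, optionally under a global sample cap with a binomial p-value
    fallback. Includes a mass-action Gillespie simulator, a finite-trace
    temporal-logic evaluator for properties over species trajectories, a
    seeded benchmark harness for error-rate and sample-size studies, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
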