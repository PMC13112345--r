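Package: memtitr
Title: Constant-pH Enhanced-Sampling Schemes and pKa Profiling on a
    Titratable-Particle Membrane Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic-titration constant-pH dynamics, pH replica exchange,
    umbrella sampling and replica-exchange umbrella sampling on an analytic
    one-dimensional surrogate of a titratable site crossing a lipid membrane,
    together with the full downstream analysis stack: WHAM potentials of mean
    force with jackknife leave-one-out errors, umbrella reweighting,
    ionized-population profiles, sliding-bin Henderson-Hasselbalch pKa
    profiles with fitting gates and Bayesian-bootstrap errors, and
    MembIT-style membrane insertion and local-deformation calculators with a
    GRO reader and a synthetic membrane-surface generator.  The surrogate has
    closed-form pKa(z), densities and free-energy profiles, so every sampling
    scheme and estimator can be verified against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
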