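Package: sorensen
Title: Revised Sorensen Whole-Body Glucose-Insulin-Glucagon Simulator
Version: 0.1.0
Authors@R: person("BioSim", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulator for the corrected Sorensen whole-body compartmental
    model of glucose-insulin-glucagon homeostasis, extended with a
    four-compartment gastrointestinal glucose transit chain for oral dosing.
    Provides intravenous and oral protocol simulation (IVGTT, IVITT, insulin
    infusion, OGTT), weighted least-squares multi-start parameter estimation
    with asymptotic covariance analysis, and Metropolis-within-Gibbs MCMC for
    a-posteriori parameter identifiability, together with synthetic
    observation generators for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
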