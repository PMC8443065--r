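Package: adaptdesign
Title: Unbalanced, Optimal and Two-Phase Adaptive Experimental Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and simulating treatment experiments where
    a balanced allocation is not the best use of a fixed sample size:
    variance-based reallocation for the two-sample Welch test, Bayesian
    c-optimal allocation for the effective concentration of a right-censored
    log-normal dose-response model, and d-/c-optimal allocation for
    detecting a synergy interaction in logistic regression.  Includes
    conditional-mean and constrained prior elicitation, random-walk
    Metropolis posterior sampling, integer allocation optimization by
    exhaustive enumeration or coordinate exchange, and seeded simulation
    harnesses for power and mean-square-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
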