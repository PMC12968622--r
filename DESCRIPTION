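Package: empbridge
Title: Model-Based Dose Bridging and Trial Design Optimisation for
    Empagliflozin in Paediatric Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation tools for extrapolating adult empagliflozin
    pharmacokinetics to children by allometric scaling of a two-compartment
    model with sequential zero- and first-order absorption. Provides virtual
    paediatric cohort generation, steady-state exposure metrics (AUC, Cmax,
    Tmax, Css), an exposure-matching dose rationale for the fixed 10 and 25 mg
    tablet strengths (including the minimum admissible body weight decision
    rule), expected Fisher-information D-optimal sparse sampling design under
    clinical visit constraints, and a simulation-re-estimation engine with a
    Laplace-approximation nonlinear mixed-effects fitter supporting
    informative and non-informative priors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
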