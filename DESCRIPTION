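Package: mabpbpk
Title: Whole-Body PBPK Modelling and Interspecies Translation for
    Monoclonal Antibodies
Version: 0.1.0
Authors@R:
    person("PBPK", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reduced whole-body physiologically based pharmacokinetic
    (PBPK) model for therapeutic IgG antibodies with two-pore
    transcapillary exchange, non-equilibrium neonatal Fc receptor (FcRn)
    salvage in the endosomal space, and an optional target-mediated drug
    disposition (TMDD) extension for soluble targets such as VEGF-A.
    Implements the sequential non-human primate to healthy volunteer to
    cancer patient translation workflow for bevacizumab-like antibodies,
    least-squares refinement of model parameters against
    concentration-time data, prediction-accuracy statistics (PE, AFE,
    AAFE), local sensitivity analysis of steady-state exposure metrics,
    and a synthetic study-data generator. A stiff Rosenbrock (Rodas3)
    integrator is provided as compiled code.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
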