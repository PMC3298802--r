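Package: ldopapk
Title: Population Pharmacokinetics of L-DOPA Blood-Brain Barrier Transport
    and Brain Metabolism in the Unilateral Rotenone Rat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population pharmacokinetic analysis of intravenous
    L-DOPA blood-brain barrier transport and its intra-brain conversion to
    the dopamine metabolites DOPAC and HVA in the unilateral rat rotenone
    model of Parkinson's disease. Implements the nine-compartment
    parent-metabolite structural model with hemisphere-specific brain
    extracellular fluid compartments, a piecewise-exact linear ODE solver,
    a Laplace (FOCE-with-interaction style) nonlinear mixed-effects
    estimation engine with empirical Bayes estimates, sequential
    parent-then-metabolite fitting, the hemisphere-symmetry model-selection
    grid with likelihood-ratio testing, microdialysis retrodialysis
    recovery calibration, tyrosine-hydroxylase staining quantification with
    responder classification, and a synthetic-trial generator that emulates
    the original study design so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
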