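Package: stochfr
Title: Stochastic Consumer-Resource Dynamics and Functional Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie direct method) of a
    minimal consumer-resource reaction network with resource immigration,
    logistic-like local growth, consumer immigration and death, handling
    pairs and interference triplets; its mean-field ordinary differential
    equations, equilibrium and bifurcation structure (transcritical and
    Hopf thresholds, regime classification); asymptotic reductions to
    classical two-dimensional predator-prey models (Lotka-Volterra,
    Rosenzweig-MacArthur, Beddington-DeAngelis); closed-form functional
    responses under chemostatic conditions (Holling type II and III and a
    predator-dependent generalization with interference); and the exact
    probability distribution of cumulative feeding events from the
    probability generating function of the chemostatic master equation,
    usable as an exact likelihood for feeding experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
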