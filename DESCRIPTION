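Package: fitscape
Title: Environmental Fitness Landscapes of a Bistable Drug-Resistance Gene Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps how inducer and antibiotic concentrations jointly shape the growth rate
    of cell populations carrying a bistable synthetic gene circuit that drives a
    bifunctional fluorescent drug-resistance protein. Processes single-cell fluorescence
    event tables into gated, smoothed expression distributions with bimodality detection
    and threshold selection; estimates population fitness from growth curves; fits
    semi-phenomenological marginal toxicity models for the antibiotic and the inducer-bound
    transactivator; estimates the nongenetic memory of high and low expression states from
    stationary distributions via directional cellular currents with fitness corrections;
    solves and fits the two-state switching population model; and predicts two-dimensional
    fitness landscapes with and without cellular memory, including the drug-resistance
    "sweet spot". Includes an exact (Gillespie) birth-switch simulator and synthetic-data
    generators with known ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
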