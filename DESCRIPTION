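Package: phenopop
Title: Population Dynamics of Interconverting Cell Phenotypes with
    State-Dependent Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a growing cell population whose members switch between a
    small number of discrete phenotypes (attractor states) while each
    phenotype proliferates at its own net growth rate.  The linear dynamics
    dN/dt = (G + K) N, with a diagonal growth matrix G and a
    Markov-generator transition part K, are analysed spectrally: the leading
    eigenvalue gives the asymptotic population growth rate and the leading
    eigenvector the stationary phenotype composition reached after
    perturbations such as FACS sorting.  Includes closed-form two-phenotype
    ratio kinetics (steady ratio, re-equilibration time course, sigmoidal
    versus saturating regimes), the m-phenotype fraction dynamics and its
    numerical fixed point, a linear-ODE simulator of cell-sorting
    re-equilibration experiments, an exhaustive grid-search fit of growth
    and transition rates to observed compositions, and a synthetic-data
    generator with compositional (Dirichlet) noise.  Ships the breast-cancer
    SUM159/SUM149 three-phenotype example models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
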