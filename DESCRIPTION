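Package: pathsem
Title: Structural Equation Modelling of Protein Degradation Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein degradation pathways from quantitative proteomics
    data by combining sequence-containment evidence with structural equation
    modelling (SEM). Builds a prior pathway graph from protein mass and
    matched-sequence containment among intact subunits and their degradation
    products, fits the implied covariance-structure model by maximum
    likelihood with chi-square, RMSEA and SRMR fit indices, refines the model
    by collapsing multicollinear protein groups into latent variables and
    backward-pruning non-significant paths, and re-estimates the selected
    model with a conjugate Gibbs sampler, monitoring convergence with
    Gelman-Rubin potential scale reduction factors (univariate and
    multivariate). Includes a linear-Gaussian synthetic-data generator and
    Rubisco degradation fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    MASS,
    numDeriv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
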