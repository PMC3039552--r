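Package: epiatlas
Title: Bayesian Small-Area Cancer Atlas Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building small-area cancer atlases: Besag-York-Mollie
    (BYM) spatial smoothing of standardised incidence ratios, a spatial
    excess-mortality (relative survival) model on collapsed person-time,
    queen-contiguity adjacency construction and repair, Geweke convergence
    screening, Tango's maximised excess events test for global clustering,
    posterior-draw aggregation to socioeconomic and rurality strata,
    five-class map categorisation, and a synthetic registry-data generator
    for end-to-end validation. Models are fitted by Metropolis-within-Gibbs
    MCMC with intrinsic CAR spatial priors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
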