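Package: sweeprate
Title: Interference Among Selective Sweeps and the Rate of Adaptive
    Substitution in Sexual Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time individual-based simulation and analytic theory for
    the rate of adaptive substitution in sexual populations experiencing
    Hill-Robertson interference among beneficial mutations.  Implements a
    haploid Wright-Fisher simulator with a continuous linear genetic map and
    Poisson crossovers, branching-process numerics for the fixation
    probability of a favorable allele near a selective sweep, self-consistent
    (Lambert-W and additive-approximation) calculators for the density of
    sweeps per Morgan, neutral-marker "painting" experiments measuring
    pairwise coalescence time under genetic draft, and infinitesimal-model
    branching simulations of fixation under unlinked fitness variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    deSolve,
    pracma,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
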