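Package: fragmodes
Title: Multilevel Selection Dynamics of Group Fragmentation Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based stochastic simulation of multispecies cell
    groups (e.g. mixed biofilms) that reproduce by fragmentation. Cells
    undergo a cooperator/cheater birth-death process with mutation at
    birth; groups undergo fission and extinction, with the fragmentation
    mode parameterized by the expected offspring-size and
    transmitted-cell fractions (s, n). Provides an exact Gillespie engine
    (compiled core), the (s, n) strategy space with truncated-Poisson
    offspring sampling, heritable fragmentation traits on a discretized
    phenotype grid, experiment protocols (strategy-space productivity
    scans, maximum-sustainable-mutation-rate estimation, sensitivity
    sweeps), independent analytic and brute-force oracles for validating
    the stochastic kernels, tidy result tables, and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    zoo,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
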