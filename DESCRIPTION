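Package: ippmc
Title: Inverse Patchy Particle Models and Grand Canonical Monte Carlo for
    Liquid-Liquid Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modelling of heterogeneously charged,
    protein-like spheres as inverse patchy particles (IPPs): an anisotropic
    overlap-volume pair potential with two repulsive polar patches and an
    oppositely charged equatorial belt, a grand-canonical Metropolis Monte
    Carlo engine with cell lists, identification of the liquid-liquid
    critical point by histogram reweighting against the universal 3D Ising
    order-parameter distribution, and connectivity observables (bonding
    volume, geometric and energetic functionality, bonded-pair energy
    distributions, cluster morphology, reduced second virial coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    pracma,
    readr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
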