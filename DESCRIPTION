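Package: dnarelay
Title: Brownian-Dynamics Models and Quantitative Analyses of ParABS
    Chromosome Segregation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic two-dimensional Brownian-dynamics simulations of
    ParB/parS partition-complex translocation in Caulobacter crescentus
    under three candidate mechanisms (pure diffusion, diffusion-binding,
    and DNA-relay, in which DNA-bound ParA-ATP dimers act as transient
    elastic tethers), together with the estimation procedures that supply
    the model parameters: chromosomal-locus spring constants from
    positional fluctuations, partition-complex diffusion coefficients from
    spot-tracking trajectories, Michaelis-Menten ATPase kinetics from
    NADH-coupled assays, cellular concentration arithmetic, and
    aspect-ratio scoring of partition-complex decompaction. Seeded
    synthetic-data generators emulate every input class so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    mclust,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
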