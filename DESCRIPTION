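Package: xointer
Title: Crossover Number and Crossover Interference in Experimental Mouse Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of meiotic crossover number and crossover interference
    from SNP-array genotypes of backcross-like (N2) offspring. Provides a
    synthetic-meiosis generator (stationary gamma renewal chiasma process with
    1/2 thinning and an optional non-interfering escape pathway), marker
    filtering and two-array harmonization, haplotype and crossover inference by
    a two-state Viterbi hidden Markov model, maximum-likelihood fitting of the
    gamma and gamma-escape (Housworth-Stahl) interference models with
    individual-level bootstrap confidence intervals and likelihood-ratio model
    comparison, a hierarchical Bayesian random-walk Metropolis sampler for
    genotype- and age-specific interference strength, and crossover-count
    summaries including a Poisson analysis of deviance and map-length
    bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
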