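Package: palmflow
Title: Parentage, Gene Flow and Spatial Genetic Structure from Mapped
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of mapped, stage-structured diploid microsatellite
    (SSR) genotype samples from natural plant populations: genetic
    diversity and inbreeding statistics with permutation tests, Loiselle
    pairwise coancestry and spatial genetic structure correlograms with
    permutation envelopes and the Sp statistic, group coancestry and
    status effective population size, categorical maximum-likelihood
    parentage with a simulation-calibrated Delta criterion, gene-flow and
    dispersal-distance summaries, and a spatially explicit neighborhood
    mating model with an exponential-power pollen dispersal kernel.
    Includes a forward simulator of mapped SSR populations with known
    pedigree for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
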