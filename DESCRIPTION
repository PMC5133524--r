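Package: trajgwas
Title: Latent-Class Blood Pressure Trajectories and Family-Based
    Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for subphenotyping longitudinal systolic blood pressure
    in extended pedigrees and testing the resulting trajectory classes for
    genetic association.  Implements a censored-normal latent-class growth
    model fitted by EM with BIC-based class selection, ranking of classes
    by cumulative hypertensive years, recursive pedigree kinship,
    REML variance-component heritability, founder-based principal
    components with LD pruning, and EMMAX-style mixed-model genome-wide
    association on pairwise and ordinal class traits.  A simulation module
    generates extended families, gene-dropped genotypes, and longitudinal
    phenotypes with latent-class and polygenic structure so that the whole
    pipeline is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    Matrix
Config/testthat/edition: 3
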