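Package: twinfam
Title: Variance Decomposition for Educational Attainment in Twin and
    Nuclear Family Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing the variance of educational attainment
    (and other continuous traits) with twin and nuclear-family data.
    Implements Falconer ACE decomposition with an assortative-mating
    adjustment and inverse-variance fixed-effects meta-analysis of
    published twin-study subgroups; model-implied covariance algebra for
    the Classical Twin Design (CTD) and the Nuclear Twin and Family
    Design (NTFD) under phenotypic-assortment and social-homogamy
    assumptions, including the intergenerational equilibrium constraint
    solver; full-information maximum-likelihood (FIML) fitting with
    saturated-model comparison, likelihood-ratio tests and iterative
    path pruning; phenotype preprocessing (qualification-to-years
    mapping, sibling age filters, age/sex residualisation, dyadic
    correlations with Fisher-z intervals); and a forward-in-time family
    simulator under assortative mating that serves as an independent
    Monte-Carlo check on the covariance algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
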