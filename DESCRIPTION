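Package: metasandy
Title: Metacommunity Assembly Analysis for Sandy-Beach Meiofauna Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of metacommunity assembly from presence/absence
    metabarcoding data on sandy beaches: OTU read-count filtering to composite
    community matrices, covariate selection (correlation pruning and stepwise
    VIF), generalised dissimilarity modelling with monotone I-splines and a
    negative-exponential link, a Monte-Carlo multivariate probit joint species
    distribution model with a second-order spatial trend surface and low-rank
    latent species covariance, Shapley-based internal-structure variation
    partitioning into environment, space and biotic-association components,
    and median quantile regressions of component shares against environmental
    and spatial distinctiveness. Includes a seeded synthetic-data generator
    emulating a beach-transect sampling design so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    withr,
    optparse
Config/testthat/edition: 3
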