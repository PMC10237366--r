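Package: nichecohesion
Title: Seasonal Cohesion of Co-Occurring Species Communities from
    Presence-Only Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures how communities of co-occurring species hold together
    across seasons. Fits presence-only minimum-volume-ellipsoid niche models
    in environmental space and projects them to binary species distribution
    models (neutral or clipped to biogeographic slopes), aggregates them onto
    a hexagonal sampling array with a tiered coverage rule to build
    presence-absence matrices, clusters species by occupancy (k-means with
    gap-statistic K selection, UPGMA visualization) and classifies
    cross-season cluster cohesion as stable, split or diffuse, computes
    Schoener's D niche similarity with randomization nulls and category
    tests, and decomposes site-by-species matrices into geographic motifs
    with a grade-of-membership model. A synthetic-landscape generator with
    known ground truth supports parameter-recovery testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    cluster,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
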