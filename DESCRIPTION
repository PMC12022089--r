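Package: glossarea
Title: Spatial-Phylogenetic Analysis of Binary Typological Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multivariate probit modelling of binary linguistic
    typological features with phylogenetic, spatial-contact,
    dispersal-path expansion and distance measurement-error components.
    Includes topographic least-cost distance construction over elevation
    rasters, along-path distance-to-entry computation, a synthetic-data
    generator with known ground truth, leave-group-out cross-validation
    with balanced accuracy, null-coefficient simulation, cartographic
    post-processing (grid marginal effects, PCA-to-RGB maps, hierarchical
    clustering, posterior overlap, feature-stability comparison), and an
    asymmetric source-to-target secondary-expansion test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
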