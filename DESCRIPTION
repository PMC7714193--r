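Package: islandiv
Title: Land-Use Effects on Alien and Native Island Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling how land use and related human pressures
    affect alien versus native species assemblages on islands, in the style
    of hierarchical site-level biodiversity syntheses. Provides a synthetic
    metacommunity generator with known effects, per-site diversity responses
    (effort-corrected total abundance and species richness with
    classification weights), ordered pairwise compositional similarity via
    asymmetric Jaccard indices with geographic and environmental distances,
    mixed-effects model fitting with random-structure selection and backward
    likelihood-ratio simplification, within-study permutation inference for
    matrix-regression style similarity models, and back-transformation of
    fitted models into percentage changes relative to minimally-used primary
    vegetation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
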