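Package: treedown
Title: Downscaling Airborne Laser Scanning Forest Inventories to Tree Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates individual-tree descriptions (species, diameter,
    height, stem count) for every 25 x 25 m cell of a forested landscape by
    combining field-plot tree lists with area-based airborne laser scanning
    (ALS) predictions of stand basal area, quadratic mean diameter and
    broadleaf proportion. Includes stratified prediction models with
    log/Box-Cox back-transformation bias corrections, a nearest-neighbour
    plot-matching and tree-list transformation algorithm with unbiased
    Bernoulli weight rounding, species-specific mixed-effects
    diameter-height models, leave-one-out cross-validation of the whole
    workflow, dominant-height comparison against canopy-height-model local
    maxima, and a synthetic-landscape generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    nlme,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    glmnet,
    withr
Config/testthat/edition: 3
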