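Package: marginalsdm
Title: Boosted Regression Tree Suitability Modelling and Marginal Land
    Accounting for Bioenergy Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A species distribution modelling pipeline for assessing global
    marginal land suitable for bioenergy crops such as Pistacia chinensis.
    Implements occurrence gridding at a common raster resolution, climatic
    envelope pseudo-absence sampling, stagewise Bernoulli-deviance boosted
    regression trees with ten-fold cross-validated tree selection, relative
    influence and partial dependence, a bootstrapped suitability ensemble
    with per-pixel uncertainty, threshold and land-use masking to extract
    marginal land, latitude-corrected spherical area accounting, and
    biodiesel volume and greenhouse-gas abatement scenario arithmetic.
    Includes a synthetic-data generator (spatially autocorrelated covariate
    rasters, a known true suitability surface, occurrence points, clumped
    land-use maps) so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
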