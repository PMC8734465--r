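Package: standmarks
Title: Marked Point-Pattern and Stand-Structure Analysis for Mapped Forest Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing ForestGEO-style mapped stem censuses: census
    ingestion and validation, quadrat grids and ESRI ASCII covariate rasters,
    stand-structure summaries (density, basal area, allometric biomass,
    diameter distributions), kernel estimators of the pair-correlation
    function g(r), the univariate mark-correlation function kmm(r) and
    Schlather's Moran's-I bivariate mark correlation Im1m2(r) with
    translation edge correction, Monte Carlo envelope tests under complete
    spatial randomness and mark-shuffling null models, focal-window abundance
    surfaces and 10-m neighbourhood predictors, conditional-inference-style
    regression trees with ensemble permutation variable importance, and a
    synthetic forest-stand generator (Thomas cluster processes thinned by a
    land-use mosaic, with crowding-dependent diameter marks) that retains its
    ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
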