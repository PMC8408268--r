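Package: treewue
Title: Tree-Ring Water-Use Efficiency, Aridity Thresholds and Nitrogen
    Deposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intrinsic water-use efficiency (W = A/gs)
    derived from tree-ring carbon isotopes in relation to aridity,
    atmospheric CO2 and nitrogen deposition. Converts delta-13C
    chronologies to W under simple and mesophyll/photorespiration-corrected
    discrimination models, derives annual climate covariates (aridity
    index, vapour pressure deficit, optional CO2-adjusted potential
    evapotranspiration), assigns sites to nominal nitrogen-deposition
    zones and builds cumulative deposition, detects the breakpoint in the
    W-aridity relationship by segmented regression, fits mixed
    multivariate models with AICc all-subsets selection and
    marginal/conditional R2, implements a stomatal-optimization model
    predicting the aridity threshold, and ships a seeded synthetic-study
    generator so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
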