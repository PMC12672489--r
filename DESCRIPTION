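Package: soilqualkit
Title: Soil Quality Indices from Minimum Data Sets with Stand Structure Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment of forest soil quality by the minimum-data-set (MDS)
    approach: principal component analysis of a total data set of soil
    indicators, norm-value based indicator selection with correlation
    pruning, nonlinear sigmoid scoring, communality-based weighting, and a
    weighted additive soil quality index (SQI) with sensitivity analysis.
    Companion stand-structure and productivity metrics (coefficient of
    variation and Gini inequality of stem diameters, allometric aboveground
    biomass, net primary productivity, broadleaf biomass share) and a
    latent-factor synthetic data generator emulating a mixed-plantation
    soil survey.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
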