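Package: abyssbio
Title: Depth Zonation and Diversity Analysis for Abyssal Megafauna Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up biogeographic analysis of benthic megafauna occurrence
    data from seabed imagery: gridded survey design with specimen-rarefied
    replicate community samples, standing-stock densities, Hill diversity
    numbers with sample-based accumulation curves, Bray-Curtis dissimilarity
    with non-metric multidimensional scaling, depth and food-supply gradient
    regressions with small-sample AIC model selection, and depth-province
    zonation statistics (morphotype overlap, exclusivity, dominance
    concentration, boundary sweep). Includes a synthetic occurrence generator
    emulating an abyssal plain with a carbonate compensation depth cut-off and
    a particulate organic carbon flux field, for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
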