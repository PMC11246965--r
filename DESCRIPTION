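Package: forestadapt
Title: Climate-Adaptation Scenarios and Ecosystem Services for Forest
    Inventory Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to project the consequences of climate-driven tree
    species turnover on forest ecosystem services at the inventory-plot
    level. Per-species probabilities of occurrence are thresholded with
    species-specific cut-offs into binary climatic suitability, five
    rule-based species-change scenarios (no adaptation, most-suitable
    species, and growth-form-preserving replacement, each with or without
    non-native taxa) are applied to plot compositions, and the resulting
    stands are scored for timber productivity, tree species richness,
    non-native share, and avalanche and rockfall protection, with
    zone-level summary reporting. A seeded synthetic-inventory generator
    emulates zone-stratified terrain, compositional species shares,
    stand volumes, and altitude-driven suitability surfaces so the whole
    pipeline can be exercised without access to confidential inventory
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
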