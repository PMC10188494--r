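Package: landshift
Title: Land-Cover Change Downscaling and Landscape Ecosystem-Service Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale pipeline coupling coarse-to-fine land-cover change
    downscaling (suitability-ranked iterative allocation with adjacency,
    physical suitability and conversion eligibility) to landscape-scale
    indicators of nature's contributions to people: pollination sufficiency
    from habitat availability around cropland, RUSLE-type soil loss, and
    compositional landscape heterogeneity. Includes scenario presets for
    area-based conservation, carbon-price driven reforestation and a
    20-percent semi-natural habitat landscape policy, and a seeded synthetic
    generator of landscapes, covariates and coarse change tables so the whole
    analysis is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
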