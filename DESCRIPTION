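Package: vmrasat
Title: Maturity Assessment Engine for Veterinary Medicines Regulatory Agencies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-assessment and benchmarking engine for national regulators
    of veterinary medicines, modelled on the tiered maturity-level approach of
    the WHO Global Benchmarking Tool. Provides a validated catalog model of
    regulatory functions, indicators and tier-designated sub-indicators; a
    sliding rating scale with exact rational scoring; strict, flexible and
    restricted-flexibility maturity-classification algorithms (Pre-bronze
    through Gold-plus) alongside a configurable WHO-GBT ML1-ML4 profile; gap
    analysis with Institutional Development Plan generation and minimal
    upgrade-path search; JSON, CSV and Markdown reporting; a synthetic catalog
    and assessment generator with brute-force classification oracles; and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
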