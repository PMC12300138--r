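Package: soilmetals
Title: Pollution Indices, Probabilistic Health Risk and Source
    Apportionment for Paired Surface and Deep Agricultural Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for heavy-metal geochemistry of paired
    surface (0-20 cm) and deep (150-200 cm) agricultural soil samples.
    Computes geoaccumulation indices, Hakanson potential ecological risk
    (Er, RI) with classification scales, deterministic and Monte Carlo
    human-health risk (hazard quotients and cancer risk over soil
    ingestion, dermal contact, inhalation and crop food ingestion via
    bioconcentration factors), and natural versus anthropogenic source
    apportionment per layer by principal component analysis (KMO,
    Bartlett, varimax) and an uncertainty-weighted positive matrix
    factorization solver. Includes a two-source synthetic data generator
    with known ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
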