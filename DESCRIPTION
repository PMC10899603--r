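Package: indikit
Title: Enzyme Stabilization Design and Process Analytics for Indican-Based Denim Dyeing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for engineering a stabilized indoxyl
    glycosyltransferase and assessing an indican-based denim dyeing process.
    Provides consensus-mutagenesis candidate calling from multiple sequence
    alignments with differential sequence logos, structure-based screens
    (geometric disulfide-pair scanning, B-factor flexible-segment detection,
    loop-graft candidate selection by anchor superposition), differential
    scanning fluorimetry melt-curve fitting and variant combination, reaction
    and photolysis kinetics (calibration, conversion, total turnover number,
    first-order decay), techno-economic costing with Monte-Carlo uncertainty,
    sensitivity and breakeven analysis, CIELAB colorimetry from spectral
    reflectance, and seeded synthetic-data generators emulating each data type.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
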