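Package: wormcompass
Title: Magnetic Orientation Analysis for C. elegans Behavioral and Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline for studying magnetotaxis in the nematode
    Caenorhabditis elegans: geomagnetic-field geometry and predicted optimal
    migration angles for vertical translation, circular statistics on worm
    heading samples (mean resultant vector, Rayleigh and V tests), two-choice
    behavioral indices (magnetotaxis and burrowing indices) with replicate
    aggregation, cross-isolate correlation of magnetotactic performance with
    local field parameters including hold-out prediction, and quantification
    of stimulus-evoked calcium responses in fluorescence traces with
    photobleach correction. Includes seeded synthetic-data generators with
    the statistical structure the analyses assume, so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
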