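Package: icefree
Title: Sea-Ice Habitat Phenology and Critical Ice-Free Events for Polar Bear Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies gridded monthly sea-ice concentration fields into
    multiyear ice, annual ice and ice-free states, computes break-up and
    freeze-up phenology and ice-free-season lengths, detects critical
    ice-free events and points of no return relevant to polar bear
    energetics, aggregates results over population regions with area
    weighting, and bias-corrects sub-monthly forcing fields against a
    reference at the monthly scale. Includes a seeded synthetic scenario
    generator emulating a downscaled high-emissions sea-ice projection for
    the Canadian Arctic Archipelago, so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
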