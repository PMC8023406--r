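Package: flowCulture
Title: Online Flow-Cytometry Monitoring of Microalgal-Bacterial Cocultures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of automated online flow-cytometry time series from
    non-axenic microalgal cultures. Reads and writes FCS 3.0/3.1 event files,
    classifies events into microalgal and prokaryotic populations by polygon
    gating on log-transformed green (FL1) and red (FL3) fluorescence,
    assembles concentration time series with growth-phase annotation, and
    quantifies prokaryotic community structure through phenotypic
    fingerprinting: concatenated bivariate kernel densities over scatter and
    fluorescence channels summarised by the Hill diversity of order two with
    bootstrap errors. A seeded synthetic coculture generator emulates
    lag/exponential/saturating growth of mixed microalga-bacteria cultures at
    25-minute sampling cadence so every pipeline stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
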