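Package: strokeangio
Title: Post-Stroke OCT-Angiography Analysis of Capillary Orientation,
    Lesion Area, and Stalling Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing optical coherence tomography angiography
    (OCT-A) of the mouse cortex after a targeted photothrombotic stroke.
    Builds decorrelation angiograms from repeated complex-valued B-frames
    with global-phase-fluctuation correction, enhances tubular vessel
    structure (tubeness and Frangi filters), quantifies capillary network
    orientation relative to the ischemic lesion center via structure-tensor
    analysis, segments the avascular lesion and tracks its area over time,
    and detects capillary stalling events on angiogram time series. A
    synthetic-data generator produces cortical vascular scenes, complex
    B-frame pairs and stall-bearing angiogram series with known ground
    truth so that every stage of the pipeline is verifiable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
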