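Package: olivecook
Title: Artificial-Vision Monitoring and End-Time Prediction for Table-Olive Lye Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the progress of the lye (NaOH) treatment of Sevillian-style
    green table olives from scanner images of phenolphthalein-stained olive halves
    arranged on an alveolar grid, and predicts the optimal treatment end time by
    anchor-corrected interpolation of the cooking curve. Provides blue-channel
    background segmentation, red/green classification of NaOH-affected flesh,
    per-olive and pooled treated-area percentages, linear, shape-preserving cubic
    Hermite (PCHIP) and modified Akima (makima) interpolants with dynamic 0%/100%
    anchors, inverse time-to-threshold prediction, relative-error benchmarking
    tables, a seeded synthetic-data generator for grid images and sigmoid cooking
    curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
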