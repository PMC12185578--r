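Package: skinDepth
Title: Depth Distribution of DAB-Stained Langerhans Cells in the Epidermis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how CD1a-positive (DAB-stained) Langerhans cells are
    distributed across the depth of the epidermis in brightfield
    immunohistochemistry sections of human skin. Provides supervised
    tissue-layer pixel classification (squamous layer, epidermis, dermis),
    construction of a relative-depth field from paired Euclidean distance
    maps, parameterised detection of DAB-positive areas, rank-based
    comparison of depth distributions between exposure conditions, a
    calibrated synthetic skin-phantom generator for validation, and
    exposure-dose arithmetic for occluded-insert skin exposures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    ranger,
    jsonlite,
    yaml,
    tiff,
    png,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
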