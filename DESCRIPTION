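Package: plaqcluster
Title: Quantification and Spatial Clustering Analysis of Amyloid Plaques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects amyloid plaques in calibrated two- or three-channel
    fluorescence images, classifies them as pre-existing, new,
    new-in-vicinity, flower-cluster members or multicore plaques, and tests
    whether new plaques deposit near pre-existing plaques more often than a
    random-placement Monte Carlo null predicts. Includes a synthetic scene
    generator with exact ground truth for benchmarking, a background-noise
    scaled detection stage, nearest-neighbour vicinity classification, a
    per-image random-placement null simulation with a matched-pairs
    comparison, and group-level nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
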