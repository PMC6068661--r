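Package: cattlescan
Title: Aerial Cattle Detection and Counting with a Multi-Scale
    Sliding-Window CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and counts cattle in nadir (top-down) UAV imagery.
    A two-class convolutional network classifies 64x64 tiles as target or
    background; the classifier is slid over each frame at three window
    scales (85%, 100% and 115% of an altitude-derived mid-range size),
    the per-window target probabilities are boosted over a 3x3 spatial
    and 3-scale neighborhood, thresholded into a binary mask, and animals
    are counted by 8-connected component labeling. Includes a seeded
    synthetic aerial-scene generator with ground truth, the rotation and
    perspective tile-augmentation recipe, SGD training of the network on
    a mean-squared-error criterion, and a reproducible end-to-end
    pipeline with PNG/CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
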