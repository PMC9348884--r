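Package: jetwatch
Title: Machine-Vision Hit/Miss Classification for Liquid-Jet Sample Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies side-microscope frames of a liquid sample-delivery jet
    at an X-ray free-electron laser as "hit" (the X-ray pulse intersected the
    jet, producing a jet explosion and a visible break) or "miss". The pipeline
    locates the nozzle by zero-normalized cross-correlation template matching,
    crops a region of interest, binarizes it with a Gaussian-weighted adaptive
    local threshold, scans the binary jet for a full-width break near the
    nozzle, and smooths per-frame verdicts with a sliding FIFO window. A
    synthetic shadowgraph scene generator provides labelled ground truth, and
    an evaluation layer computes confusion counts and Dice coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
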