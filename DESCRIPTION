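Package: complexr
Title: Perceived Visual Complexity from Pairwise Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning two-alternative forced-choice ("which image is
    more complex?") judgements into per-image complexity scores via Bayesian
    two-player skill updates, and for predicting those scores from scalar
    image statistics, image parts and object annotations. Includes balanced
    comparison-design generation, a synthetic observer and procedural image
    world for end-to-end validation, a battery of classical complexity and
    clutter features (grey-level co-occurrence, colourfulness, entropies,
    feature congestion, edge density, JPEG compressibility, keypoint and
    region counts), cross-validated regression harnesses, disc-based
    decomposition of images with bicubic complexity maps, and predictors
    built from bounding-box object tags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    grDevices,
    tools,
    xml2,
    jsonlite,
    glmnet,
    e1071,
    EBImage,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
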