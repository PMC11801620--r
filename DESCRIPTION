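Package: fibrilseg
Title: Random-Forest Segmentation and Morphometry of Collagen Fibrils in
    Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trainable pixel classification for grayscale transmission
    electron micrographs of extracellular-matrix collagen. A small filter
    bank (Canny, Roberts, Sobel, Scharr, Prewitt, Gaussian, median) feeds a
    random-forest classifier that labels each pixel fibril or background;
    classifier output is smoothed, thresholded and split into connected
    instances, and each fibril cross-section is measured by an equal-area
    moment ellipse whose minor axis is taken as the diameter. Includes
    consensus (2-of-3 reviewer) ground-truth construction, IoU-matched
    precision/recall/F1 evaluation, percent-error and parity-R2 agreement
    statistics, and a seeded synthetic micrograph generator with known
    per-fibril truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
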