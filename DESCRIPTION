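Package: aestex
Title: White-Box Hierarchical Modeling of Perceived Aesthetic Emotions of
    Visual Textures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts perceived aesthetic emotions of visual textures from
    computed low-level image features using an interpretable, hierarchical
    feed-forward model. Extracts a fixed catalog of 106 descriptors per
    texture (HSV color means, gray-level co-occurrence matrix statistics,
    Tamura perceptual features, and wavelet energy signatures), ranks them
    with neighborhood component analysis for regression, aggregates
    semantic-differential rating panels with outlier screening, evaluates a
    frozen published reference model bit-exactly, and re-fits the three-layer
    hierarchy by basis expansion with greedy, complexity-penalised term
    selection. Includes procedural texture and rating-panel simulators with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
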