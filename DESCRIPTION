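Package: moascreen
Title: Mechanism-of-Action Enrichment for Image-Based Co-Culture Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for image-based morphological profiling of
    cancer/fibroblast co-culture drug screens: merging overlapping
    fields of view into well-level images, retrospective illumination
    correction, percentile intensity normalization, single-cell crop and
    feature extraction from segmentation label masks, well-level
    aggregation with robust per-plate (median/MAD) normalization and
    Z-prime plate quality control, and a permutation-based
    mechanism-of-action enrichment statistic (GSEA-style running sum over
    correlation-ranked well profiles). Includes a synthetic-data
    generator (plate layouts, rendered three-channel well images with
    ground-truth cancer masks, and MOA-structured feature tables) so the
    full pipeline is testable without any raw screen data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr,
    pracma,
    tiff,
    EBImage
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
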