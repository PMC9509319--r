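Package: wsikit
Title: Whole-Slide Image Analytics: Reading, Stain Processing, Patch
    Inference, Annotation Storage and Tiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for computational pathology on
    whole-slide images (WSIs). Provides unified random-access reading of
    pyramidal TIFF slides and flat visual fields in physical units
    (microns-per-pixel, objective power), virtual pyramids for derived
    rasters, Otsu-based tissue masking, grid and point patch extraction,
    stain separation and normalization (Reinhard, Macenko, and a
    dictionary-learning variant with ordinary-least-squares concentration
    estimation) plus stain augmentation, a model-agnostic patch-inference
    engine with result merging and slide-level pooling, a spatially
    indexed annotation store with a restricted predicate language and
    standard-format round trips, hybrid location-plus-feature graph
    construction, and Zoomify tile pyramid generation. A fixture module
    synthesizes pyramidal slides and Beer-Lambert stained images with
    known ground truth so every subsystem is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    jpeg,
    EBImage,
    DBI,
    RSQLite,
    jsonlite,
    deldir,
    yaml,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    digest,
    xml2,
    covr
Config/testthat/edition: 3
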