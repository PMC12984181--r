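Package: bccmap
Title: Co-Localized Dermoscopy and LC-OCT Margin Mapping for Basal Cell
    Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping basal cell carcinoma (BCC) margins by
    co-localizing narrow-field probe surface images within a wide-field
    dermoscopy image.  Implements scale- and rotation-invariant keypoint
    detection and descriptor matching, RANSAC rigid registration with an
    inlier-count reliability gate, inter-frame motion tracking with a
    dead-reckoning fallback, incremental dermoscopic mosaicking, patch-based
    lesion-probability heatmaps with a blue-to-yellow score colormap, and
    score-colored trajectory overlays with per-quadrant margin coverage
    reporting.  A phantom-synthesis module generates dermoscopy-like
    textures, simulated probe streams with ground-truth poses, and synthetic
    B-scan-like frames so the whole pipeline can be validated against known
    ground truth without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
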