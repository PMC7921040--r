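Package: elemap
Title: Segmentation and Morphological-Feature Analysis of LA-ICP-MS Element Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of quantitative laser ablation inductively
    coupled plasma mass spectrometry (LA-ICP-MS) element maps of small
    biological specimens such as zebrafish embryos. Imports per-pixel
    intensity tables (delimited text or an HDF5 time-of-flight subset) and
    annotated morphological features, registers the annotation frame onto
    the laser stage frame with an affine transform, rasterizes features
    into overlapping region-of-interest masks, segments the maps with six
    clustering algorithms (k-means, mean shift, affinity propagation,
    spectral clustering, DBSCAN, HDBSCAN), cross-tabulates clusters against
    regions into count-share, mean-intensity and summed-amount heatmap
    layers, computes per-region descriptive statistics, converts intensity
    to amount via linear calibration with detection limits, and quantifies
    replicate reproducibility via Spearman rank correlation of heatmaps.
    A deterministic synthetic-embryo generator makes the whole pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    kernlab,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
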