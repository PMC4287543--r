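Package: clonetrack
Title: Segmentation, Tracking and Lineaging of Proliferating Cells in 5-D Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying clones of motile, proliferating cells
    (e.g. neural stem cells imaged together with vasculature) in 5-D
    (x, y, z, t, channel) confocal time-lapse data. Provides channel-specific
    background noise removal, translational montage registration of
    overlapping 3-D tiles with maximum-spanning-tree offset resolution,
    3-D segmentation with anisotropy-aware distance maps and convex hulls,
    windowed multitemporal association tracking, lineage tree construction
    with per-frame cell-to-vessel distances and cleavage planes, validation
    edits (Gaussian-mixture splits, deletions) with forward propagation,
    and a synthetic 5-D movie and montage generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    mclust,
    stats,
    grDevices,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
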