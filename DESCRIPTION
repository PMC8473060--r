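Package: stemseg
Title: Individual Tree Segmentation for Ground-Based LiDAR Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments individual trees from terrestrial (backpack/handheld)
    LiDAR point clouds. The pipeline filters far-range outliers with the
    scanner trajectory's convex hull, normalizes heights against a
    morphologically derived digital terrain model, detects stems by DBSCAN
    clustering of a breast-height trunk slab, partitions the cloud by
    iterative per-tree cylinder voxelization with 3D subclustering, merges
    floating crown segments into ground-connected stems and filters residual
    noise by a distance threshold. Includes a reference-versus-algorithm
    tree matching procedure with detection rate, commission and omission
    error metrics, a parameter-sensitivity sweep, and a synthetic forest
    scene generator with per-point ground truth for end-to-end testing.
    Reads and writes LAS 1.2, PLY, XYZ/CSV point clouds and trajectory CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
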