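Package: bunch3d
Title: Grape Bunch Architecture Phenotyping from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated extraction of grape bunch architecture traits from dense
    3D point clouds. Scans in PLY format are voxel-downsampled, segmented into
    smoothly connected regions by normal-based region growing, and individual
    berries are detected by iterative RANSAC sphere fitting with overlap-based
    suppression of duplicate models. Seven bunch traits are exported per scan
    (berry number, mean berry diameter, mean and total berry volume, convex hull
    volume, bunch width and bunch length), together with configurable bunch
    compactness factors rank-correlated against visual OIV 204 classes. A
    ground-truthed synthetic bunch generator emulating 360 degree and partial
    (single-side) scans supports validation without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
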