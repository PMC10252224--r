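Package: facemark3d
Title: Coarse-to-Fine Prediction of 3D Facial Soft-Tissue Landmarks from Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic localization of 32 named facial soft-tissue
    landmarks on 3D surface scans. A facial point cloud is normalized to the
    unit cube, voxelized to a binary occupancy tensor, and processed in two
    stages: a volumetric convolutional network first detects axis-aligned
    bounding boxes for six facial regions (eyes, nose, lips, chin, right face,
    left face), then a per-region volumetric regression network with a
    residual stage predicts each region's landmark coordinates, which are
    mapped back to millimetres through the recorded normalization transform.
    Includes a parametric synthetic face generator with analytically known
    landmark ground truth, combined mean/max regression losses, point-cloud
    readers and writers (PLY, OBJ, XYZ-CSV), and millimetre-scale evaluation
    summaries (per-landmark mean and standard deviation, threshold coverage,
    left-right symmetry gaps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
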