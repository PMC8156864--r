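Package: schooltrack
Title: Parallel Multi-Fish Tracking with Shape-Index Feature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online tracking of fish schools in backlit video. Individual fish
    are detected from background-subtracted blobs by two redundant
    shape-index (Hessian curvature) features: the head as a spherical-cup
    region at a coarse Gaussian scale, and the body centerline as a bundle
    of Hough ridge lines clustered with DBSCAN, whose angular spread gives a
    single-valued motion state. Identities are maintained by two cooperating
    SORT-style trackers (constant-velocity Kalman filters, IOU cost,
    Hungarian assignment, temporary-track lifecycle): a primary head tracker
    and a secondary body tracker that recovers head positions when the head
    detection fails, e.g. during occlusions. Includes a synthetic fish-school
    generator with exact ground truth, the standard multi-object tracking
    metrics (precision, recall, occlusion rate, correct tracking and
    identification ratios, identity switches), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
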