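Package: spinemark
Title: Two-Step Vertebral Landmark Localization and Spinopelvic Angles for
    Sagittal Spine Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies thoracolumbar vertebrae (C2-S1 levels) in sagittal
    spine radiographs and localizes the four corner landmarks of each
    vertebral body with a two-step coarse-to-fine pipeline: a multi-label
    presence classifier and a global corner localizer on the whole image,
    followed by per-vertebra crop refinement, all using differentiable
    spatial-to-numerical transform (DSNT) heads over spatial heatmaps.
    Derives L1-L5 and L1-S1 lordosis and sacral slope from the corners.
    Includes a synthetic radiograph simulator with exact ground truth, a
    compact trainable convolutional backbone for CPU-scale experiments,
    coordinate-aware augmentations (caudal field-of-view crops, rotations,
    flips, elastic deformation), and an evaluation suite (normalized corner
    errors, per-level medians and weighted means, PCK curves, detection
    accuracy, Bland-Altman angle agreement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
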