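Package: fracture3d
Title: Fracture Detection and 3D Visualization from CT Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for locating bone fractures in computed tomography
    (CT) series and displaying them on a 3D reconstruction of the bone.
    Reads and writes single-frame CT DICOM series, segments cortical bone by
    Hounsfield-unit thresholding, extracts a capped watertight bone surface,
    lifts per-slice 2D fracture bounding boxes into physical-coordinate 3D
    masks using pixel spacing and slice thickness, and overlays the fracture
    mask on the bone mesh (glTF scene plus PNG snapshot). Ships a
    deterministic rule-based cortical-gap detector, a CSPDarknet-53/SPP/PAN
    one-stage (YOLO v4 style) detector scaffold with a toy training loop, an
    object-detection evaluation suite (IoU, greedy matching,
    precision/recall, PR curves, average precision), and a synthetic CT
    phantom generator with ground-truth annotations so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
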