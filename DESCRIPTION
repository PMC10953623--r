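Package: ventmorph
Title: Deformation-Free Ventricular Morphometry and Dementia Screening
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segmentation of the lateral ventricles on T1-weighted-like 3D
    brain volumes by patch-based label fusion in a stereotaxic template
    space, extraction of ventricular shape and volume features (ICV-
    normalized total volume, anterior-posterior ratio split at the coronal
    y = -12 mm plane, left-right frontal and temporal log-ratios), and a
    trainable linear support-vector classifier flagging subjects as
    compatible or not compatible with behavioural variant frontotemporal
    dementia. Includes affine registration to the template, automated
    segmentation quality control, confusion-matrix and likelihood-ratio
    reporting, and a synthetic phantom generator that makes the whole
    pipeline testable without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
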