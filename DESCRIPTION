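Package: panfrax
Title: Mandibular Fracture Detection on Synthetic Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable re-implementation of a combined mandibular-fracture
    detection pipeline for panoramic radiographs: ELU U-Net fracture-line
    segmentation, a second tooth-region U-Net whose inverted and dilated
    output suppresses false fracture lines inside the tooth row,
    luminance-adaptation-style contrast enhancement and geometric
    augmentation, a pluggable bounding-box detection stage with YOLO-format
    annotation I/O, box-line fusion with duplicate-box removal, and a
    precision/recall/F1 evaluation protocol without true negatives. Because
    clinical radiographs are not redistributable, the package ships a
    synthetic phantom generator that emulates the mandible arch, six
    anatomical fracture classes, three fracture morphologies and the tooth
    row, with paired ground-truth masks and annotations, so every stage is
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
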