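Package: lumenseg
Title: Shape-Prior Level-Set Segmentation of the Carotid Lumen in
    B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variational segmentation of the carotid-artery lumen in
    longitudinal B-mode ultrasound images. Implements distance-regularized
    level-set evolution (DRLSE) and the Chan-Vese model as baselines, and a
    shape-prior-guided level-set model in which an adaptive band around the
    vessel centerline, generated fully automatically from a rough Otsu
    segmentation, constrains the evolving contour. Includes the automatic
    initialization pipeline (Otsu threshold, largest connected component,
    morphological wall extraction, centerline and narrowest-radius band),
    five segmentation metrics (Dice, Hausdorff distance, sensitivity,
    specificity, IoU), a speckle ultrasound phantom generator with exact
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
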