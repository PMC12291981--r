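Package: densecount
Title: Density-Aware Non-Maximum Suppression and Counting Evaluation for
    Crowded Animal Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and evaluation toolkit for detection-based
    animal counting in crowded pens. Implements IoU-family box scores with
    center-distance and shape-disparity penalties (PIoU and its
    attention-weighted v2 loss), hard non-maximum suppression, Soft-NMS
    with Gaussian confidence decay, and a density-aware suppression
    pipeline that selects the suppression strategy from the raw detection
    count before counting by direct enumeration. Ships a detection
    matching and metric suite (precision, recall, F1, average precision
    from the interpolated precision-recall envelope, scene-level counting
    accuracy, MAE, RMSE), a synthetic crowded-scene generator with a
    detector-noise model for end-to-end testing without image data, and
    readers and writers for YOLO-format label files and COCO-style
    detection JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
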