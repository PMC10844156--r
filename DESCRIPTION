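Package: annotagree
Title: Inter-Annotator Agreement for Bounding-Box Detection Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates agreement between multiple annotators who mark
    detections (e.g., carious lesions on bitewing radiographs) with
    axis-aligned bounding boxes, in settings where no gold standard exists.
    Implements a centroid-based box correspondence relation, a greedy
    one-to-one matching algorithm, pairwise error counts and pooled
    matched IoU, majority-vote consensus standards with tentative
    (minority) lesions and leave-one-out panels, precision/recall/F1
    against a designated reference annotator, and Wilcoxon signed-rank
    significance testing of paired per-image differences. Includes
    readers and writers for CVAT-for-images XML and COCO detection JSON,
    and a seeded simulator of annotator panels with controllable
    sensitivity, false-positive rate, localization jitter and box-size
    bias for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
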