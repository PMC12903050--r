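Package: chipcell
Title: Cell Detection and Killing-Assay Quantification for Microfluidic Trap Arrays
Version: 0.1.0
Authors@R: person("chipcell", "maintainers", email = "maintainers@chipcell.dev", role = c("aut", "cre"))
Description: A facile pipeline for detecting suspension cells in bright-field
    images of microfluidic trap-array chambers. Provides a synthetic scene
    generator with exact bounding-box ground truth (chambers, whole arrays,
    and paired bright-field/fluorescence time-lapse assays), a trainable
    two-stage region-proposal cell detector, a circular-Hough-transform
    baseline, a bounding-box evaluation kit (IoU, greedy matching,
    precision/recall, average precision, training-size and annotator
    studies), whole-array chamber cropping with oversize/edge filtering,
    time-lapse cell-killing-assay quantification (constant-count detection,
    ROI fluorescence, bimodal live/dead thresholding, trajectories, survival
    curves), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
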