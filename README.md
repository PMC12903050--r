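# chipcell

Cell detection and killing-assay quantification for microfluidic trap
arrays, in R.

## What this is for

Suspension cells (lymphoblasts, T cells) trapped in microfluidic chamber
arrays are imaged in bright-field for counting and time-lapse assays.
Classical image processing struggles here: the PDMS-water refractive-index
mismatch draws high-contrast channel-wall contours through every image,
imaging conditions drift between sessions, and chambers hold 1-15 cells
including touching clusters. `chipcell` provides the full analysis
pipeline for this setting, exercised end to end on synthetic scenes with
exact ground truth:

* **synthetic scene generation** — chambers (four layouts, 1-3 outlet
  channels), whole-array mosaics, and paired bright-field/fluorescence
  time-lapse assays, with per-image intensity RSD matched to the 15-27%
  seen in practice and exact bounding-box ground truth
  (`make_chamber_scene`, `make_array_image`, `make_timelapse_assay`);
* **a trainable two-stage region-proposal detector** — multi-scale
  circular-gradient proposals plus a trained classification/refinement
  head; epoch budget 200, stop at a total-loss plateau below 0.15
  (`train_detector`, `infer`, `filter_by_confidence`);
* **a circular-Hough baseline** with the conventional 5-100 px radius band
  (`detect_circles`);
* **the evaluation protocol** — IoU on half-open boxes, greedy one-to-one
  matching at IoU >= 0.5, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
  all-point average precision with precision-at-0.9 reported alongside,
  plus training-set-size and annotator-variability study runners
  (`iou`, `match_detections`, `precision_recall`, `average_precision`,
  `run_training_size_study`, `run_annotator_study`);
* **whole-array cropping** — chamber detections filtered for oversized and
  edge-touching boxes, crops with exact offset round trips
  (`split_array`, `map_to_array_coords`);
* **killing-assay quantification** — `N_total` at t0 (confidence >= 0.9),
  constant-count detection at later timepoints (trapped cells cannot
  escape), per-cell ROI fluorescence, live/dead threshold at the local
  minimum of the bimodal end-point histogram, trajectories and survival
  curves (`count_t0`, `select_constant_count`, `bimodal_threshold`,
  `build_trajectories`, `survival_curve`, `run_assay`);
* **a CLI** — `synth | train | infer | hough | eval | split | assay |
  study-size | study-annotators` behind `chipcell_main()` (launcher in
  `inst/exec/chipcell`), with provenance records for reproducibility.

Annotations are Pascal-VOC XML (1-based inclusive, converted to the
package's 0-based half-open convention on read); inferences are flat CSV
(`image_id, x_min, y_min, x_max, y_max, label, confidence`); COCO JSON is
readable; images are plain-text PGM.

## Worked example

```r
library(chipcell)

# 1. a training set of synthetic chambers (all four layouts)
train <- synth_dataset(30, seed = 21, n_cells_range = c(1L, 10L))
sum(sapply(train, function(s) nrow(s$boxes)))          # 135 annotations

# 2. fine-tune the detector
fit <- train_detector(train, train_config(seed = 5))
length(fit$loss_history)                               # 200 epochs
tail(fit$loss_history, 1)                              # 0.03365111

# 3. held-out evaluation
test  <- synth_dataset(20, seed = 999)
preds <- lapply(test, function(s) infer(fit$model, s$pixels))
gts   <- lapply(test, function(s) s$boxes)
res   <- average_precision(preds, gts, iou_threshold = 0.5)
round(c(AP = res$ap, precision_at_0.9 = res$precision_at,
        recall_at_0.9 = res$recall_at), 4)
#>               AP precision_at_0.9    recall_at_0.9
#>           0.9985           0.9861           0.9467

# 4. one chamber at the standard operating point (confidence 0.9, IoU 0.5)
sc  <- make_chamber_scene(scene_spec(n_cells = 5, seed = 4242))
det <- filter_by_confidence(infer(fit$model, sc$pixels), 0.9)
match_detections(det, sc$boxes, iou_threshold = 0.5)
#> <match_report> TP=5 FP=0 FN=0 (IoU >= 0.50)

# 5. the conventional circle-detection baseline on the same chamber
match_detections(detect_circles(sc$pixels), sc$boxes)
#> <match_report> TP=5 FP=45 FN=0 (IoU >= 0.50)
```

Reading the numbers: the trained detector's loss plateaus well below the
0.15 stopping level; on 20 unseen chambers it reaches an average precision
of 0.9985 at IoU 0.5 and, at the 0.9 confidence cutoff, 98.6% precision;
the 5-cell chamber is detected perfectly. The Hough baseline finds the
five cells too but buries them under 45 false positives triggered by
channel walls and cell texture — the failure mode that motivates a trained
detector in this imagery.

## Layout

```
R/                      implementation
tests/testthat/         unit, property, and acceptance suites
scripts/acceptance.R    acceptance report entry point
vignettes/              methods and design notes
inst/exec/chipcell      CLI launcher
```
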