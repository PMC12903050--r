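---
title: "chipcell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipcell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Suspension cells trapped in microfluidic chamber arrays are imaged in
bright-field for counting and longitudinal assays. Detection is harder than
it looks: the PDMS-water refractive-index mismatch renders channel walls as
high-contrast double-edge contours that confound intensity-based
segmentation, imaging conditions drift between sessions (focus, noise,
illumination), and chambers hold anything from a single cell to a touching
cluster of fifteen. `chipcell` implements a bounding-box detection pipeline
for this setting — detector, conventional baseline, evaluation protocol,
whole-array cropping, and killing-assay quantification — exercised entirely
on synthetic scenes with exact ground truth, so every claim a test makes is
checkable against a planted truth.

## The synthetic world

`make_chamber_scene()` renders one chamber: a bright/dark double-edge wall
contour (four layouts differing in chamber size and 1-3 outlet channels),
`n_cells` textured disks (bright rim, darker annulus, mottled cytoplasm —
the bright-field halo appearance near focus), Gaussian defocus blur, and
noise. Key stated conditions and the defaults that encode them:

* **Pixel scale** — 0.65 um/px (a 10x objective on a typical sCMOS chip),
  so a ~15 um lymphoblast is ~23 px across and a ~10 um T cell ~15 px; 20x
  is emulated by doubling diameters. The imaging literature for this regime
  quotes cell sizes in um without a pixel scale, so one had to be fixed.
* **Cell count** — 1 to 15 per chamber, the occupancy range of these trap
  arrays. `random_scene_specs()` additionally caps the draw at the
  layout's packing capacity (random sequential placement jams near a
  packing fraction of ~0.45), since a 15-cell draw cannot physically fit
  the smallest layout at lymphoblast scale.
* **Contact rule** — minimum center distance `0.9 * (r_i + r_j)`: touching,
  slightly interpenetrating clusters occur (the hard case for detection)
  but never full overlap.
* **Image noise** — per-image intensity relative standard deviation (RSD)
  targeted in [0.15, 0.27], the spread observed across real sessions in
  this regime; the generator scales structural contrast down and adds
  Gaussian noise to land within +-20% relative of the target (verified over
  100 random specs in the suite).
* **Time-lapse assay** — cells are trapped and cannot escape, so
  bright-field frames differ only in noise realization and the total count
  is constant; this is the assumption the constant-count analysis exploits.
  Fluorescence is a two-Gaussian model (live mu 0.15, dead mu 0.85, common
  sigma 0.05, arbitrary units): a caspase-3/7-style reporter brightening in
  dying cells, separated by >4 sigma so the end-point histogram is bimodal.
  The number dead at frame t is `floor(fraction * n_cells)` exactly.

What the generator does **not** emulate: physical optics (no PSF), cell
deformation or motility, photobleaching, illumination vignetting, debris,
and real annotator noise. A green test therefore establishes that the
pipeline's *logic* recovers planted truth under realistic geometry and
noise — not that any particular accuracy transfers to a given microscope.

## The detector

The production tool this package mirrors fine-tunes a two-stage
region-proposal network (Faster R-CNN: ResNet-50 backbone, feature pyramid,
region-proposal stage, classification/refinement head) from COCO-pretrained
weights. No deep-learning runtime is available in this package's
environment, so `chipcell` keeps the *two-stage structure* and contracts
while using classical components sized to the synthetic world:

1. **Proposal stage** — Sobel gradient magnitude correlated with
   one-pixel ring kernels over a radius grid (FFT correlation; scale
   anchors derived from the training boxes). Cells present a closed
   gradient rim, so responses peak at cell centers at the matching scale.
   A textured cell also excites its internal edges, so each peak takes the
   *largest* near-maximal radius — the outer contour. Local maxima (up to
   150 per image) become candidate boxes.
2. **Head** — each candidate, resampled to a 12x12 patch with 25% context,
   yields standardized pixels plus log-area, relative contrast, a radial
   ring profile, and the angular variance of the outer ring (low for
   radially symmetric cells, high for wall corners). A logistic classifier
   scores candidates; four ridge regressors refine center and log-size,
   exactly the role of the refinement head. Non-maximum suppression
   deduplicates.

Training labels candidates by IoU against ground truth (>= 0.5 positive,
< 0.3 negative, mid-range discarded — the standard proposal-head protocol),
adds jittered ground-truth boxes and random background boxes (so walls and
outlets populate the negative pool), and augments with the four axis flips.
Optimization is seeded full-batch gradient descent with momentum
(lr 0.2, momentum 0.9, L2 1e-3 — chosen on a held-out synthetic set during
development, as the upstream tool's hyperparameters are unpublished).

**Stopping rule.** Training runs the epoch budget (default 200) and then
stops at the first epoch whose trailing 10-epoch mean loss is below
`stop_loss` (default 0.15), capped at twice the budget. Both conditions are
required: stopping at *whichever comes first* was tried and produced
underfit models whose loss had crossed 0.15 while held-out AP was still
climbing. The plateau level 0.15 is the conventional "significantly
trained" level for this task family.

Determinism is a seeded, single-threaded contract: all stochastic steps run
under a private RNG stream, and inference uses no RNG at all.

## Evaluation protocol

* `iou()` uses continuous half-open box coordinates, so area is
  `(x_max - x_min) * (y_max - y_min)` with no off-by-one; a detection is
  valid at IoU >= 0.5.
* `match_detections()` is greedy and confidence-ordered (the VOC protocol):
  one-to-one, ties between ground-truth boxes broken by lower index,
  confidence ties by `x_min` then `y_min`. The brute-force optimal
  assignment lives in the test suite as an oracle, where the greedy TP
  count must match it on >= 95% of random small instances.
* `precision_recall()` returns exact ratios with the conventions
  precision = 1 when nothing was predicted and recall = 1 when there is
  nothing to find.
* `average_precision()` is the all-point-interpolated area under the pooled
  PR curve swept over every distinct confidence. Because greedy matching is
  prefix-consistent, the sweep is computed incrementally; a test pins it to
  an exhaustive per-threshold re-matching oracle. Reports in this domain
  sometimes quote "AP" at a fixed 0.9 confidence cutoff, so
  precision-at-threshold is computed and reported alongside, never
  conflated.
* Pooled TP/FP/FN counting across images is the default (per-image
  averaging is exposed via the per-image report in the CLI); which of the
  two a given publication used is rarely stated.

## Killing-assay analysis

`N_total` is fixed at t0 by the 0.9 confidence cutoff. At later timepoints
`select_constant_count()` keeps exactly the `N_total` highest-confidence
detections — implemented as top-N selection rather than a threshold search,
which is equivalent but deterministic under ties — and reports the
confidence of the last kept box as the effective threshold. Trajectories
are greedy nearest-center links (cells are near-stationary; no appearance
model), ROI fluorescence is the mean over the half-open detection box, and
the live/dead threshold is the local histogram minimum between the two
fluorescence modes (50 bins, 3-bin moving-average smoothing; neither value
is standard in the literature, both are exposed).

Two robustness choices in `bimodal_threshold()` deserve note, both found
necessary on sparse histograms (~100-200 cells in 50 bins): the partner
peak is selected by *valley depth* rather than raw height (a bumpy single
mode offers only shallow valleys; a genuine second mode must also carry
>= 10% of the primary peak's weight), and among tied minimal bins the one
nearest the midpoint of the two peaks is returned — the stable estimator of
the equal-density crossing, to which the procedure converges within one bin
width as n grows (tested at n = 5000). When no admissible valley exists the
function refuses and instructs a manual threshold rather than guessing.

The dead call is `fluorescence >= threshold` (the reporter brightens), and
the absorbing dead state (once dead, always dead — the trapped-cell
assumption) is on by default but can be disabled, since whether analyses in
this domain enforce it or merely assume it is usually unstated.

ROI means over detection boxes are diluted by background (a box is ~pi/4
cell by area), so the detected dead mode sits below the generator's dead
mean; the bimodal threshold adapts since both modes dilute together. ROI
size is recorded but does not feed the live/dead call.

## Whole-array cropping

`split_array()` operationalizes two filters whose thresholds are not
standardized anywhere: "oversized" means area above 1.5x the median
detected chamber area, and "on the edge" means any box side within 2 px of
the image border (chambers partially out of the field of view). Both are
flags. Crops carry their global offsets; `map_to_array_coords()` /
`map_to_crop_coords()` are exact inverses, so downstream cell boxes map
back losslessly.

## Circular-Hough baseline

The conventional baseline is a textbook circular Hough transform: Sobel
magnitude, Otsu-thresholded edge map, an `(cx, cy, r)` accumulator built by
FFT ring correlation with votes normalized by ring circumference, peak
non-maximum suppression over a radius-scaled neighborhood, and the radius
band filter (5-100 px). Duplicate suppression (centers within `0.5 r` of a
stronger peak) is configurable down to 0 to *reproduce*, not hide, the
classic several-circles-per-cell failure mode. The upstream tool's
sensitivity setting is unpublished, so the quantitative baseline comparison
here is qualitative by design.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; only the VOC
  layer converts (VOC is 1-based inclusive). Non-integer coordinates are
  rounded half-up on VOC write. One-pixel VOC boxes are rejected as
  degenerate.
* Images are numeric matrices in [0, 1]; single-channel input is the norm
  and `h x w x 3` arrays are averaged to one channel. External image I/O is
  ASCII PGM (P2, 16-bit; P5 readable) — the environment provides no
  TIFF/PNG codec, and PGM keeps every artifact plain text.
* Seed-derived sub-seeds are computed in double precision modulo 2^31 - 1
  to avoid 32-bit overflow.
* Placement failure after bounded rejection sampling is an explicit error,
  never a partial scene; an empty chamber-detection set yields an empty
  crop list with a warning, not an error.

## Known limitations

* The detector is a classical stand-in matched to the synthetic world; on
  real micrographs a true convolutional two-stage detector is expected to
  dominate it. Its contracts (training loss plateau, confidence filtering,
  AP recovery) are what transfer.
* The annotator-variability study uses perturbed ground truth (jitter,
  dilation) as synthetic annotators; real annotator disagreement is richer.
* Single-annotation training already scores well here because synthetic
  cells are homogeneous; the gap between 1 and 40 annotations is therefore
  smaller than on real data, though the ordering is preserved and tested.
* The survival analysis assumes well-separated fluorescence modes; heavily
  overlapping modes trigger the unimodal refusal path.
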