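---
title: "Counting eosinophils on whole slides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting eosinophils on whole slides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoescan)
```

## The clinical problem

Eosinophilic esophagitis (EoE) is diagnosed and monitored by counting
eosinophils in esophageal biopsies: a slide is called *active* when at least
one 400X high-power field (HPF, 0.3 mm²) contains 15 or more **intact**
eosinophils — cells showing both their intensely eosin-red cytoplasmic
granules and a nucleus. Degranulated material and cells without a visible
nucleus (**not-intact** eosinophils) look similar but are excluded from the
diagnostic count. The peak eosinophil count (PEC) is the maximum intact count
over all HPF positions on the slide.

Doing this by eye is slow and inter-observer variability is substantial, not
least because a whole-slide image (WSI) has $10^8$–$10^{10}$ pixels while the
diagnostic features are single cells. `eoescan` implements the full
computational pipeline: multi-label segmentation plumbing, area-based
counting, a sliding-HPF PEC scan with bounded memory, activity
classification, the per-image evaluation metrics and competition-rank model
selection used to pick the segmenter, and a synthetic-slide generator with
exact ground truth so every stage is testable end to end without clinical
data.

## Pixel geometry

All coordinates are 0-based `(row, col)` and regions are half-open
`[r, r + h) × [c, c + w)`, which makes tiling arithmetic exact. The default
scale anchors on the HPF correspondence: a 0.3 mm² field spans 2144 × 2144 px,
i.e. `pixel_scale()` ≈ 0.25549 µm/px and a field side of ~548 µm. We anchor on
the area–pixel pairing rather than the rounded 548 µm figure because the
latter is itself a rounding of $\sqrt{0.3}\,\mathrm{mm} = 547.72\ \mu m$;
anchoring on 548/2144 would make the recovered pixel side come out one pixel
short (2143) of the stated 2144.

`plan_tiles()` supports two edge policies. `exact` demands that the grid end
flush with the extent (used for the 1200 → 9 × 448/376 training crop and the
2144 → 25 × 448/424 window crop); `clamp` appends one flush-right/bottom tile
per axis for arbitrary extents. Overlap duplication is harmless because
patch masks are recombined by OR (`fuse_masks()`), which is commutative and
idempotent.

## From point annotations to masks

Experts annotate eosinophil *centers*, not outlines. `rasterize_annotations()`
expands each center into a closed disk of 50 px diameter (1961 px once
rasterized — we use `≤` on the squared distance, keeping the area near the
2050 px typical-cell figure and inside the counting band below). Patches are
optionally filtered on their background (glass) fraction; because the
direction of that filter is genuinely ambiguous as usually stated, both
readings are implemented (`drop_below`, the literal reading and default, and
`drop_above`, the tissue-poor reading) and the choice is a config field.

## Segmentation

The segmenter is a *contract*: any callable that maps an RGB tile (plus its
absolute offset, which pixel-free oracles need) to a three-class softmax
probability map. Pixels become labels via `threshold_probabilities()`: a
pixel is assigned to the argmax eosinophil class only when that probability
reaches 0.5, resolving the ambiguity between per-channel sigmoid thresholds
(which can produce overlapping labels) and pure argmax — the combined rule
guarantees at most one label per pixel.

The reference trainable model is a compact nested encoder–decoder
(UNet++-style): a three-level encoder, dense re-designed skip pathways, and
two deep-supervision heads averaged at inference, written directly in R with
im2col convolutions and Adam. The loss is `1.0·Dice + 0.5·BCE`, each averaged
over the two eosinophil classes; the Dice term is smoothed with ε = 1 in
numerator and denominator, the standard stabilisation for empty masks. The
learning rate follows cosine annealing from `lr_max = 1e-3` to 0 over the
scheduled epochs (defaults: 100 epochs, batch size 5, 448 px tiles at stride
376 for the full-scale recipe). Checkpoints are selected on a *per-image*
validation metric — by default the arithmetic precision/recall mean
`m(0.5P + 0.5R)`, the metric that wins the model-selection ranking below.
Per-image (rather than per-batch) averaging matters because most patches
contain no eosinophils at all, and batch-pooled metrics drown the rare
positives.

Network width and depth default to a deliberately small operating point
(width 8, three levels) so that training runs on a single CPU; the segmenter
is pluggable, so a heavyweight externally-trained model drops in behind the
same contract. For pipeline testing, `oracle_segmenter()` emits the ground
truth (optionally corrupted at a controlled per-pixel flip rate,
deterministic in the seed and tile offset), which separates "is the plumbing
exact?" from "is the model good?".

## Counting and the PEC scan

Counting is area-based over connected components (8-connected by default,
4-connected available): a component with area ≤ 1800 px counts 0, one in
(1800, 3000] counts 1, and beyond 3000 px each additional 2000 px adds one
cell. The increment is `floor` by default ("each additional 2000 px" read as
requiring the full increment); `ceil` is available. The band brackets the
typical single-cell area (~2050 px) and turns merged neighbours into
plausible multi-cell counts.

`peak_eos_count()` slides a 2144 px window at a 500 px stride (clamp policy,
so edge windows stay flush and contain real tissue). Each window is processed
*lazily*: only its own pixels are fetched from the slide source, cut into
448 px patches at stride 424 (25 per window), segmented, OR-fused, and
counted — peak memory is one window plus one patch, never the decoded slide.
Ties take the first maximal window in row-major order. Slides smaller than
one HPF are scanned as a single window covering the slide. Not-intact counts
are computed and reported (for the peak window) but never contribute to the
PEC or the activity call, matching the clinical rule; `classify_activity()`
partitions exactly at 15 (14 is inactive, 15 active).

No installed R reader exposes per-tile TIFF region decoding, so file-backed
sources decode once on first access; the windowed memory contract is honored
structurally through the `slide_source` accessor abstraction, and synthetic
or programmatic sources are served truly lazily.

## Evaluation machinery

Segmentation quality uses four per-image, per-class means over pixel
confusion counts: mIoU, mPrecision, mRecall, mSpecificity. Zero-denominator
terms (ubiquitous, since many patches are empty) follow a configurable
convention: *score* (default) awards 1 when the situation is vacuously
perfect (empty truth and empty prediction) and 0 otherwise; *skip* drops the
term. Model selection over candidate segmenters uses competition ("1224")
ranking per metric — ties share a rank and the next rank skips by the tie
count, the scheme that reproduces the published tie patterns exactly — with
the Mean Rank averaging the six classification-metric ranks (count error is
ranked but excluded) and the Final Rank ranking the Mean Ranks.

`roc_sweep()` sweeps activity thresholds at midpoints between distinct PECs
(plus sentinels), reporting trapezoidal AUC and the smallest
accuracy-maximizing threshold; with counts faithful to truth labelled at the
≥ 15 cutoff, that threshold lands at 14.5. `count_calibration()` is ordinary
least squares of predicted on true counts plus the mean absolute error;
`segment_error_stats()` matches predicted to true components greedily by
overlap (one truth per prediction, deterministic tie-breaks) to give a
component-level false discovery rate and a counting error rate normalized by
`max(true count, 1)` — that denominator is our stated choice, since the rate
is otherwise undefined on empty images.

## The synthetic-slide generator

`generate_slide()` is the package's study-condition generator, not a mere
fixture. It plants intact/not-intact cells (minimum center separation 56 px,
so annotation disks stay disjoint; 26 px border margin, so disks are never
clipped), optionally in dense clusters confined to one HPF-sized window that
is snapped onto the scan grid — making the planted cluster count *exactly*
attainable by one scanned window. Scattered intact cells keep one full HPF
side of clearance from every cluster window so no scan window can mix
cluster and stray intact cells; not-intact cells roam freely because they
never enter the PEC. Ground truth (masks, per-window counts on the same
clamped grid the scanner uses, true PEC and peak window) is computed by a
brute-force whole-slide scan that shares no code with the lazy windowed
path, which is what makes PEC-recovery tests meaningful.

Two deliberate appearance choices:

* **Masks follow the annotation protocol.** Ground-truth masks are the 50 px
  annotation disks at the planted centers (area 1961 px, always in the
  one-cell band), while the rendered granule core radius jitters ±20% around
  25 px. This mirrors how the real labels are made (clicked centers expanded
  to fixed disks, not traced outlines), makes planted counts and
  mask-derived counts agree exactly, and keeps the label geometry consistent
  for the toy model. The cost is that rendered cell appearance and label
  boundary are not pixel-identical — exactly as with the real protocol.
* **Classes are separable by design.** Intact cells render as red granular
  cores with a purple nucleus blob inside a pale cytoplasm disk; not-intact
  cells as duller, sparser granule fields without a nucleus. The generator
  aims to support oracle-driven pipeline tests and small-model training, not
  histological realism: no stain variation, scanner artifacts, tissue
  architecture, or intraepithelial compartments. Passing tests on synthetic
  slides therefore demonstrates the *pipeline's* exactness and the model's
  trainability, not clinical performance.

## Problem sizes and numerical choices

The shipped experiments run at deliberately modest scale, chosen as a
realistic CPU workload: the PEC-recovery suite uses twenty 2600² px slides
at the reference operating point (2144 px HPF, stride 500, 448/424 patches);
toy training uses ~200 64-px tiles, width 8, 8 epochs with `lr_max = 3e-3`
(cosine-annealed), which reaches held-out mIoU well above 0.8 on the
synthetic classes. Dice ε = 1; BCE probabilities are clamped at 1e-7;
softmax is computed with max-subtraction; exact probability ties between the
two eosinophil classes resolve to intact. Degenerate inputs error loudly:
tiles larger than their extent, non-divisible exact grids (the residue is
named), annotations outside the extent, overcrowded placement requests,
single-class ROC inputs, and constant-truth calibrations.

## Known limitations

* The trainable segmenter is a compact reference implementation for
  CPU-scale experiments; matching clinical-grade segmentation quality
  requires an external model behind the segmenter contract.
* File-backed slides are decoded whole on first access (see above); true
  tile-level lazy decoding would need a region-capable TIFF reader.
* The generator does not emulate stain variation or tissue context, so
  model scores on synthetic tiles overstate what the same architecture
  would achieve on real biopsies.
* Metrics carry no uncertainty quantification (no bootstrap CIs); the
  package reports point values.
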