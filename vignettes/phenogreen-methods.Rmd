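---
title: "Methods: multi-plant greenhouse image phenotyping with phenogreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-plant greenhouse image phenotyping with phenogreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogreen)
```

## The problem

Large greenhouse experiments monitor many plants with many fixed overhead
cameras. Each image shows a group of ten potted plants (two rows of five)
on dark circular plates, anchored by a white QR fiducial in the middle of
the group. Because tables and cameras move during an experiment, pot
positions cannot be assumed fixed: each image must be re-analysed from
scratch — find the pots, identify which physical plant sits in each
position, correct the color, segment the plants, and accumulate per-plant
time series of projected area (a biomass proxy) and hue (a greenness /
nitrogen-status proxy).

phenogreen implements that pipeline end to end, together with a synthetic
scene generator that provides exact ground truth, so every stage is
testable without access to greenhouse images.

## Synthetic scenes

`renderScene()` draws a light-gray table, dark plates (value < 0.2),
plants, and a white QR square with black interior modules. Plants are
unions of five overlapping "leaflet" ellipses rather than disks, so masks
have concavities and overlap metrics are not degenerate. Every leaflet
contains the pot center; scaling a plant about its center is therefore
set-monotone and truth areas never decrease as a plant grows.

Plant pixels are sampled in HSV with hue inside `plantHue ± 10°`,
saturation in [0.4, 1] and value in [0.4, 0.9]. Two restrictions are
deliberate:

* hue is clipped to [55°, 150°]. Hues in [30°, 55°) pass the HSV rule but
  can fail the CIELAB `a* ≤ −4` rule at some saturation/value combinations
  (verified by grid search over the 8-bit gamut), and the generator's
  contract is that truth pixels pass *both* rules, enabling exact-recovery
  tests;
* value stays at or below 0.9 so that plant pixels never rival the QR
  white under a multiplicative color cast, keeping the fiducial the
  brightest structure in the image.

Sampled colors are quantized to 8 bits and re-checked; the rare boundary
failures are resampled and finally forced to a mid-green. Empty pots are
rendered with no plate at all, which makes them undetectable by
construction. Decoy pots (`extraPots`) extend the two rows sideways,
outside the QR hull, to exercise group selection.

All randomness flows from two seeds: `seed` fixes the geometry (leaflet
layout, plate shades, QR pattern) and `noiseSeed` the per-pixel color
sampling. `renderSeries()` keeps `seed` fixed and varies `noiseSeed` per
capture, so a longitudinal series has stable geometry with fluctuating
pixel noise — emulating a fixed camera over a growing plant. Captures are
spaced evenly in 10:00–17:00 (14/day reproduces a half-hour schedule) and
named `<cameraId>_MT%Y%m%d%H%M%S.png`, a fixed-width format whose
lexicographic order is chronological.

What the generator does *not* emulate: perspective and lens distortion,
specular reflections, shadows, plant overlap between neighbouring pots,
occluded fiducials, and non-multiplicative lighting changes. Passing the
synthetic recovery tests therefore demonstrates the pipeline's
bookkeeping, geometry and color arithmetic — not robustness to real
greenhouse imagery, which in the original setting is the job of trained
neural detectors and segmenters.

## Detection and grouping

Detection is pluggable: any function `image -> box table` can serve.
The bundled `referenceDetector()` finds plates by dark-disk response and
the QR by white-square response, with thresholds relative to the image's
99.9% brightness quantile so it works before color correction (the
pipeline order is detect → correct → segment). Detected boxes use 0-based
half-open pixel coordinates, which compose with array slicing without
off-by-one corrections.

`selectGroup()` clusters pot boxes into rows by 1-D gap clustering on the
vertical centers, with the median box height as the gap threshold — a
deliberate alternative to k-means-style clustering of plant pixels, which
is unreliable when neighbouring plants differ greatly in size. Within each
run of adjacent rows, boxes are clustered into columns the same way, and
all contiguous five-column windows are enumerated. A window is admissible
when the QR center lies inside its bounding hull; among admissible windows
the one whose centroid is nearest the QR wins. The tie-break is our
choice; the selection rule itself ("contains the QR, most likely group")
leaves it open. Failures are typed errors — "QR not found", "group not
identified" — that the batch pipeline logs and counts rather than
propagates.

`assignBarcodes()` rotates grid positions by the camera's orientation
(0/90/180/270°) into NS/EW coordinates inside the camera's block and looks
up each pot's barcode, so a physical plant keeps its identity regardless
of how the camera was mounted. `cropPots()` cuts fixed-size, zero-padded
crops centered on each box so area measurements are comparable between
pots; the default 512 px matches the U-net's input contract (a multiple
of 2), and smaller studies can use any even size.

## Color correction

The QR's white background is the white reference: inside the QR box,
pixels whose value channel reaches the box's 75th percentile are taken as
white (the black modules fall below), and each channel is stretched by
`255 / mean` with clipping and half-up rounding. The black modules are
deliberately not used as a black reference. One numerical subtlety: the
multiplication happens before the division (`pixel * 255 / mean`) so exact
halves round up rather than falling victim to floating-point
representation error. A box without contrast — fully black, fully white,
or degenerate — raises a typed "white reference unreliable" error. The
correction is white-point-only; a pure multiplicative cast is inverted up
to quantization (±2 intensity levels), which the generator invariants
check.

## Segmentation

The threshold rule is the conjunction of two colorspace gates: HSV hue in
[30°, 150°] with saturation and value in [0.2, 1] (yellow through green,
excluding pale and dark pixels), and CIELAB `a* ≤ −4` with `b* ≥ 4` (a
green and a yellow component; D65 white point, 2° observer — the sRGB
standard, since the choice is otherwise open). Both bounds are inclusive.
The two gates fail in different places and their conjunction cancels most
single-space leakage. We read the CIELAB description as requiring both
components (AND, not OR); an OR reading would admit blue-green and orange
pixels that the prose explicitly excludes. Conversions are delegated to
grDevices (`rgb2hsv`, `convertColor`); the test suite checks the resulting
masks pixel-by-pixel against scalar re-implementations, treating pixels
that land numerically *on* a threshold (about 0.1% of random 8-bit pixels)
as ambiguous at float precision.

### U-net

The optional learned segmenter is a small canonical U-net: `depth` = 4
encoder levels of two 3×3 conv + ReLU blocks (base 16 channels, doubling
per level), 2×2 max pooling, a two-conv bottleneck, nearest-neighbor
upsampling followed by a 3×3 conv, skip concatenation, and a 1×1 sigmoid
head trained with binary cross-entropy and Adam (learning rate 1e-3,
batch size 1), prediction threshold 0.5. These hyperparameters are fixed
here as a deliberately small design so CPU training is feasible;
convolution forward/backward passes are compiled (Rcpp/Armadillo) and
verified against finite differences in the tests.

Training data can be expanded by the deterministic 40-fold augmentation:
{flip, no flip} × {0°, 90°, 180°, 270°} × {identity, four 460×460 corner
crops rescaled to 512×512} — an exhaustive enumeration, so no variant
repeats. The validation split (20%) happens before augmentation; 40 pairs
become 32 training and 8 validation pairs, 1,280 and 320 after
augmentation. The augmentation order (flip → rotate → crop) only affects
variant labels, not the set of variants.

## Segmentation scoring

From pixel confusion counts: IoU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN),
pixel accuracy, precision, recall, and F1 from precision and recall. Dice
is implemented in the standard form, which restores the identities
Dice = 2·IoU/(1+IoU) and F1 ≡ Dice; both are asserted to 1e-12 in the
tests. When a denominator is zero the score is 1 if both masks are empty
and 0 otherwise, keeping metrics defined on empty pots. AP at 0.5 IoU
sorts predictions by confidence, greedily matches each to its best
unmatched truth instance, and integrates the envelope of maximum precision
at recall ≥ r (all-point interpolation, the modern PASCAL VOC
definition). Whole-crop masks are treated as instances.

## Traits

Per plant, captures are grouped by calendar date: the daily area is the
**median** of the day's captures (robust against plant movement), the
daily variance is their sample variance, and the daily hue is the mean of
the per-capture mean hues. Days whose variance exceeds
`mean + 3·sd` of all day variances — computed globally across the plant
set, which we read as the intended disambiguation of "three standard
deviations from the mean" — are dropped.

**AreaPerDay** standardizes the growth curve by subtracting the first
day's median (plants start from cuttings of varying size), integrates it
by the trapezoidal rule over a 30-day window with gaps linearly
interpolated, and divides by the window length. The window is anchored at
the first observed day (the series start is inoculation in the intended
design; the anchor is otherwise unstated).

**Hue statistics** use the arithmetic, not circular, mean and variance:
the mask confines hue to [30°, 150°], far from the 0°/360° wrap, so
circular statistics would change nothing while complicating the
regression below. **RateOfHue** is the OLS slope of the 3-day
centered-rolling-mean hue over days 3–23 after inoculation ("the first 20
days, starting from day 3 due to the rolling mean"); the smoothed hue at
day 3 is **StartHue**. Positive rates indicate greening, i.e. established
symbiotic nitrogen fixation. Rolling means are centered with edge
truncation to avoid phase lag in the slope.

**Heritability.** Trait tables are filtered (uninoculated "NO" controls,
contaminated strains, explicitly excluded plants) and passed to
`lme4::lmer` with fixed effects NS + EW + Round + Replicate (plus StartHue
for RateOfHue, which is strongly correlated with the rate) and random
intercepts for clover and rhizobium genotypes. Broad-sense heritability is
each variance component over the sum of the three
(`h2FromVarComps()`). The delegation to lme4's REML machinery is
deliberate: this package owns only the data preparation and the
heritability formula. The model formula contains no initial-size term —
the standardized AUC already removes initial size.

## Uptime reporting

Expected images are `days × images/day` per camera and `× cameras` in
total; uptime is received over expected. Percentages are carried exact
internally and rounded half-up only at presentation, since the published
accounting mixes integer percentages with 2-decimal per-camera averages.
Unparseable filenames are collected and reported, never silently dropped,
and report regeneration over the same inventory is byte-identical.

## Batch pipeline and concurrency

`runPipeline()` maps each image through detect → select group → white
balance → assign barcodes → crop → segment → observe, appending one row
per pot to `area.csv` and `greenness.csv`. Appends go through an
exclusive lock implemented with atomically created lock directories with
bounded backoff, so concurrent workers neither lose nor interleave rows;
the contract (4 writers × 250 rows → exactly 1,000 intact rows) is
asserted in the tests. Workers parallelize over images, never within one,
and the final files are rewritten in sorted order, so output is a pure
function of the inputs regardless of worker count. With a U-net
configured, the run splits into preprocess / predict / postprocess passes
with intermediate crops on disk, mirroring how one would isolate the
prediction stage on dedicated hardware.

## Problem sizes and numerical choices

The test and acceptance workloads use scenes with plate radius 16 px and
plant radius 6.5 px (about 270×150 px per image, 40 px crops), a 30-day ×
14-capture series with 10 px/day area growth and 2°/day hue drift, 200
seeded scenes with 0–4 decoys for the grouping property, and a 20-pair,
5-epoch, 64 px U-net smoke run (depth 4, base 16). These sizes were chosen
as the smallest at which every geometric feature of the full-scale setup
(row/column structure, QR hull containment, crop padding, cast-induced
threshold failure) is still exercised. Heritability recovery is simulated
at the experiment's genotype counts (148 clover × 170 rhizobium) with
variance ratios 0.33/0.04/0.63.

Other fixed numerical choices: half-up rounding wherever 8-bit values are
produced; quantile type 7 (R's default) in the white reference; strict
inequality in the variance filter so an all-equal set keeps every day;
greedy AP matching by best IoU with ties broken by first index; and a
fallback mid-green color after eight rejection-sampling rounds in the
generator (never observed to trigger in practice, but it bounds the
loop).

## Known limitations

* The reference detector is built for synthetic scenes; real images need
  a trained detector plugged into `detectCandidates()`.
* Group selection assumes the QR sits inside the target group's hull; a
  displaced fiducial yields "group not identified" rather than a guess.
* The white balance is single-reference and multiplicative; it cannot
  correct mixed illumination or clipping introduced upstream.
* Hue-based greenness is a relative measure; absolute nitrogen content
  would require external calibration.
* The U-net here is CPU-sized; it demonstrates the training and
  prediction contracts, not state-of-the-art segmentation accuracy.
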