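---
title: "Counting reproductive structures on herbarium sheets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting reproductive structures on herbarium sheets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocount)
```

## The problem and the model

Digitized herbarium sheets carry a phenological signal — how many buds,
flowers, and fruits a specimen bore when collected — that is expensive to
harvest by hand. The cheapest reliable human annotation is a *dot*: one
point per visible structure, placed near its center. `phenocount` turns
those dots into data a detector can learn from, and turns detections back
into evaluated counts.

The central modeling commitment is **counting by detection**: the predicted
count ĉ of organ k on specimen i is the number of detector instances of
class k. There is no density estimation, no direct count regression, and
deliberately no spatial deduplication of detections: if the detector splits
one flower into two instances the pipeline over-counts by one, and if it
merges two touching flowers it under-counts by one. The evaluation
framework is designed to make exactly those failure modes visible.

The second commitment is the **dodecagon surrogate mask**. A dot gives
location but not extent. Because most reproductive structures of the herbs
this workflow targets are roughly circular when pressed, a regular 12-gon
inscribed in a circle of calibrated radius is a good compromise between a
crude bounding box and an unobtainable manual outline. Radii are calibrated
per (genus, organ) as the arithmetic mean of the enclosing-circle radii of
a few manually segmented examples — five per pair is the recommended
protocol, and `calibrate_radius()` warns below it. The 12-gon's area has
the exact closed form 3r², which the test suite uses as a geometry oracle.

## Pipeline stages and their parameters

**Resizing (`plan_resize`).** Working resolution is long edge ≤ 1024 px,
short edge ≤ 600 px. A fixed target like this can be read two ways: a fixed
(distorting) output size, or an aspect-preserving fit. We chose the
aspect-preserving rule `s = min(1024/long, 600/short)`, including uniform
*upscaling* of smaller sources, because the radius calibration assumes
roughly isotropic structures; anisotropic scaling would turn circles into
ellipses and silently invalidate the calibrated radii. Annotations are
stored in original-image coordinates (0-based, x rightward, y downward) and
transformed on demand, so a change of resize policy never invalidates the
raw annotation tables.

**Mask generation (`build_dodecagon`, `rasterize_polygon`).** Vertex 0 sits
at east, vertices counter-clockwise every 30°; orientation is a pure
convention since all downstream metrics are rotation-invariant. Masks are
clipped to the image rectangle by Sutherland–Hodgman polygon clipping,
never wrapped. Rasterization uses the pixel-center-in-polygon rule on the
half-open grid [0, W) × [0, H); encodings are uncompressed column-major
run-length lists that round-trip losslessly.

**Anchor sizes (`derive_anchor_spec`).** Region-proposal detectors must
propose boxes at scales that cover every mask. The ladder of powers of two
starts at or below the smallest dodecagon's across-flats side (2·r·cos 15°)
and extends to at least the largest diameter (2·r), with aspect ratios
{0.5, 1, 2} as a conventional default.

**Detection (`baseline_detector`).** The deterministic baseline segments by
color: pixels within `color_tol` (max per-channel difference, default 0.12)
of an organ's palette color, grouped by connected components, discarding
components under `min_area` px (default 20 — about half the area of the
smallest synthetic bud, so real organs survive and single-pixel speckle
does not). A component's confidence score is the fraction of its pixels
within the strict half-tolerance; on noiseless synthetic sheets every score
is exactly 1. "Training" this backend means fitting the palette — the
median color in a 5×5 window around each training dot, per organ — on the
training split only, which makes per-species, global, and transfer
scenarios all meaningful on a CPU. The default confidence threshold is
`tau = 0.5`; it is a free parameter of `filter_detections()` and every
scenario config. The backend contract (a `detect()` method returning the
fixed detection schema) is what a learned instance-segmentation model would
implement; its training is out of the package's scope by design.

**Evaluation (`counting_error`, `mae`, `r_squared`, `letter_values`,
`presence_dominance`).** Sign convention: error = predicted − true. Two
readings of "overall MAE" coexist: summing absolute errors over organs per
specimen before averaging, versus averaging the three per-organ MAEs. The
comparison-table convention in this field is the latter, so `mae()` reports
it as its `"all"` row (the per-specimen-sum reading is available via
`overall = "sum_per_specimen"`; with all three organs present it is exactly
three times larger). R² uses the mean of the *observed* counts of the
evaluated subset and is reported as `NA` when the truth is constant
(SS_tot = 0) rather than ±Inf. Letter values follow the successive
half-sample depth rule: the median at depth (1+n)/2, each subsequent letter
at (1 + ⌊previous⌋)/2, symmetric from both ends, stopping at depth 1 or
after 8 letters; points beyond the outermost letter pair are outliers.
Presence indicators are `count ≥ 1`; dominance indicators are the
inequalities "flowers ≥ buds" and "fruits ≥ flowers" with ties — including
0 = 0 — satisfying them. TP/FN rates are percentages of observed positives,
TN/FP of observed negatives, and the overall accuracy is the
prevalence-weighted combination, which is an exact identity before
rounding. Columns with no observed positives (or negatives) carry `NA`
rates instead of dividing by zero. Reported percentages are rounded to 1–2
decimals only at the table surface; raw values are retained internally.

**Crowd aggregation (`aggregate_annotators`, `compare_sources`).** Counts
from several annotators of one specimen are combined either by taking a
single seeded "isolated" annotator per specimen or by per-organ arithmetic
averaging kept *fractional* — rounding averaged counts would discard
precisely the variance reduction averaging buys. `mae_by_annotator()`
scores each annotator on their own specimens and averages over annotators,
the natural reading of an "isolated annotator" table row. Source
comparisons use a two-sided Wilcoxon signed-rank test on paired
per-specimen mean absolute errors (exact for small untied samples, normal
approximation otherwise): counting errors are integer-valued and
heavy-tailed, so a t-test's normality assumption would be hard to defend.
Identical error vectors short-circuit to p = 1.

**Dataset splitting (`split_specimens`).** The unit of splitting is the
specimen — all of a specimen's annotations travel together — via a
seed-controlled uniform shuffle and prefix cut of size
`round(fraction · n)`. One published dataset using this design reports a
3073-specimen collection split 2457 + 615, which sums to 3072; the
arithmetic cannot be reproduced exactly from the stated numbers, and the
package documents rather than resolves that discrepancy.

## The synthetic generator: what it does and does not emulate

`generate_specimen()` renders a beige sheet with green stem/leaf clutter
and organ blobs: flowers as 5-lobed light-pink blobs, buds as small dark
ellipses, fruits as mid-dark disks — sizes and colors chosen so that
detectability tracks organ size and visual distinctiveness, as it does on
real sheets. Per-organ counts follow a hurdle (zero-inflated) Poisson:
present with probability (0.0975, 0.8292, 0.20) for (bud, flower, fruit),
and 1 + Poisson(0.642, 1.401, 1.112) structures when present. Those
defaults were fixed once, from the marginal statistics of a large real
phenology collection: they give expected organ proportions of
6.2 / 77.4 / 16.4 percent, about 2.6 structures per sheet (sparse sheets,
which is why counting-by-detection is preferred over density methods here),
and rare buds (≈90% of sheets have none). Sheets are generated directly at
600 × 1024 px. Dot markers are recorded at the exact centroid of each
instance mask; truth masks are stored as run-length encodings.

What the generator deliberately does **not** emulate: photographic noise
and lighting variation (a `noise_sd` parameter exists but defaults to 0),
occlusion of organs by leaves, morphological variability within an organ
class, faded or discolored specimens, and labels/barcodes. Consequently, a
perfect score on synthetic data shows that the *pipeline machinery* —
coordinates, masks, counting, metrics — is correct, not that any detector
will perform well on real imagery. The two synthetic "species" with shifted
palettes emulate only the *direction* of the cross-species transfer effect
(a model trained on a differently-colored species misses structures, so
out-of-species R² drops below in-species R²), not its magnitude.

## Numerical choices and degenerate inputs

- Composition percentages with a zero grand total are `NA`, never NaN.
- `rasterize_polygon` on a polygon fully outside the image warns and
  returns an empty mask rather than failing.
- Placement of non-overlapping organs uses rejection sampling with a
  300-try budget per instance and a 6 px separation margin; exhaustion is a
  classed error, since silently dropping a requested structure would
  corrupt the ground truth.
- Radii are stored in resized-image space; calibration measured on original
  images must be pre-multiplied by the resize scale.
- A missing (genus, organ) radius entry is a configuration error naming the
  pair; an opt-in fallback to the organ-level mean exists but is off by
  default, because silent fallbacks hide calibration gaps.
- All randomness flows through explicit integer seeds (`withr::with_seed`);
  no function mutates the global RNG state.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every property observable while keeping runs quick on one
CPU: 5–12 sheets for unit-level round trips, 60 sheets for the end-to-end
exact-counting experiment, 30 sheets for the two-species transfer
comparison, and 1,000 count draws for distributional checks of the
generator (proportions within ±2 percentage points; chi-square
goodness-of-fit on the hurdle-Poisson bins).

## Known limitations

- The baseline detector is a pipeline oracle, not a model of real imagery;
  conclusions about real specimens require a learned backend implementing
  the same contract.
- Dodecagon masks assume roughly circular structures; elongated organs
  (spikes, racemes) would need a different surrogate geometry.
- One dot maps to one instance: the pipeline cannot represent several dots
  on one physical structure or one dot spanning several structures.
- The dominance indicators compare only adjacent phenophase pairs; a full
  phenophase index (e.g. ratio-based staging) is downstream of the counts
  this package produces.
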