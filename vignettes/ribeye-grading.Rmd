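---
title: "Methods: rib-eye morphometry, marbling and five-level grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rib-eye morphometry, marbling and five-level grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribgrade)
```

## The measurement model

The package assumes the standardized capture situation that makes
photographic grading defensible in the first place: a single trimmed
rib-eye cross-section lying flat on a dark matte bench, photographed
perpendicularly under even lighting, saved as an 8-bit sRGB raster, with a
physical length reference visible in the frame. Everything downstream is
deterministic given the saved file and the configuration; there is no
interactive thresholding and no colour management (the capture protocol,
not the software, is assumed to control illumination and white balance).

The pipeline is a programmatic rendering of a classic interactive
image-analysis session:

1. **Scale.** Two pixel points on the reference plus its known length give
   `px_per_cm` (`calibrate_scale()`); one global scale applies to the whole
   frame. All areas count whole pixels — a pixel is inside or outside a
   mask, with no sub-pixel weighting.
2. **Grayscale.** `to_grayscale()` averages R, G, B by default (the
   unweighted RGB→8-bit conversion of the reference interactive tool);
   Rec. 601 luma weights are available by flag. The choice matters little
   for segmentation here because fat/lean/background separate strongly in
   both.
3. **Auto contrast.** `auto_contrast()` computes, from the 256-bin
   histogram, the lowest cut with at most `saturated_fraction/2` of pixels
   strictly below it and the highest cut with at most that fraction
   strictly above, then linearly rescales the cut range to [0, 255] with
   clamping. The default saturation of 0.35% is the conventional "auto"
   value. The stretch is monotone, so it can never reorder intensities —
   thresholding after the stretch selects the same pixel population more
   robustly, it does not change what is selectable.
4. **Threshold.** `isodata_threshold()` implements intermeans iteration:
   starting from the midpoint of the populated range, `t` is repeatedly
   replaced by the rounded mean of the two class means it induces. Because
   both class means are nondecreasing in `t`, the update map is monotone
   and the iteration converges to a fixed point (a defensive cycle guard
   exists but is unreachable under monotone rounding). The rib-eye is the
   class strictly above the threshold (bright object on a dark bench).
5. **Cleanup.** Internal holes are filled, components smaller than
   `cleanup.min_object_cm2` (default 1.0 cm² — bench debris, the scale bar)
   are removed, and the largest connected component is kept, so the
   rib-eye mask is always a single connected region.
6. **Marbling.** The same intermeans rule is applied to the histogram of
   grayscale values *inside* the rib-eye mask; fat is the brighter class,
   and the marbling mask is intersected with the rib-eye mask by
   construction.
7. **Particle analysis.** `particle_analysis()` labels 8-connected
   components (the particle-analyzer convention; hole filling uses the
   4-connected background dual), filters them to a calibrated size range,
   and sorts survivors by area with centroid `(y, x)` tie-breaks.

### Measured parameters

* **Length/width** come from the minimum-area oriented bounding rectangle
  of the mask, computed over pixel *corners* (so an axis-aligned
  `1000 × 500` px rectangle measures exactly `1000 × 500`), via rotating
  calipers on the convex hull. This is the deterministic analogue of the
  manual protocol — calipers on the longest part, and on the widest part
  perpendicular to the fibre direction — and is exactly testable on
  rectangles; a maximum-Feret alternative is available by flag.
* **Area** is the calibrated mask pixel count.
* **Marbling percentage** is the size-filtered fat particle area divided by
  the *total* cross-section area (not the lean-only area; the denominator
  convention is not universal, so it is stated here and fixed).
* **Colour** is summarized as the mean of each channel over the full
  rib-eye mask, fat included, and the ratio `mean_r / (mean_r + mean_g +
  mean_b)` is formed from the means (mean-of-channels, not mean of
  per-pixel ratios — the order of operations matches a channel-histogram
  workflow). The three channel ratios partition: they sum to one exactly.

## Grading

`default_grading_table()` holds the five-level standard: area bands
40–50–60–75–90–∞ cm², marbling bands 0–10–30–50–70–100%, and colour-ratio
bands 0.49/0.47/0.45/0.43 in decreasing orientation. Printed standards
share interval endpoints between adjacent grades; the package resolves
them deterministically as half-open intervals, lower-inclusive for the
increasing parameters and upper-inclusive for the decreasing ratio, so a
shared endpoint always falls to the lower grade index (area 50 → A2,
ratio 0.49 → A2). A coverage test asserts every in-scale value receives
exactly one grade at 0.01 resolution, endpoints included.

Two genuinely open design points are decided here and flagged in output:

* **Sub-scale areas.** The scale starts at 40 cm²; smaller cuts are
  flagged `below_scale` rather than silently clamped to A1 (clamping is
  available by flag).
* **Conflicting parameter grades.** Source grading tables typically assume
  the three parameters co-vary; no combination rule is printed anywhere
  authoritative. The default is majority-then-marbling: a grade shared by
  at least two parameters wins, otherwise the marbling grade (the dominant
  quality indicator) decides, and a spread above one grade raises a
  `disagreement` flag. This rule is provably monotone in the marbling
  grade. `marbling_only` and conservative `minimum` strategies are
  selectable, and the strategy used is always recorded in the result.

## Tunable parameters

| Key | Default | Units | Why |
|---|---|---|---|
| `grayscale.mode` | `unweighted` | — | fidelity to plain RGB→8-bit conversion |
| `autocontrast.saturation` | 0.0035 | fraction | conventional auto-contrast saturation |
| `threshold.method` | `isodata` | — | deterministic replacement for manual thresholding; `fixed` overrides |
| `particles.min_cm2` | 0.5 | cm² | floor filtering dust/fascia fragments; the printed "0.5" carries no unit, the calibrated-cm² reading is adopted and echoed in every run log |
| `particles.max_cm2` | Inf | cm² | upper size bound |
| `cleanup.min_object_cm2` | 1.0 | cm² | removes bench debris before the largest-component rule |
| `marbling.min_separation` | 20 | gray levels | see below |
| `grading.strategy` | `majority_marbling` | — | see above |

The 0.5 cm² particle floor deserves emphasis: it is large relative to fine
marbling flecks, so under the calibrated-units reading small flecks do not
count toward the marbling percentage. The floor is configurable precisely
because the unit convention is consequential.

`marbling.min_separation` is a guard this package adds: on a uniform lean
sample the intermeans rule would happily split pure sensor noise into two
classes and report roughly half the muscle as "fat". If the two
within-muscle class means are closer than 20 gray levels — far below any
real lean/fat contrast under controlled lighting, far above the split that
noise with sd ≈ 3 can produce — the sample is treated as uniform lean: an
empty marbling mask with a `low_contrast` flag. A strictly degenerate
(single-bin) histogram is flagged `degenerate_histogram` the same way.
Both are valid samples, not errors.

## The synthetic generator

`generate_sample()` renders what the pipeline needs to be true of its
inputs and nothing more: a smooth convex-ish silhouette (an ellipse with a
low-amplitude three-harmonic boundary perturbation), a fat-blob network of
random clipped ellipses grown by rejection sampling until the realized
within-silhouette fat fraction is within one percentage point of target,
flat grade-typical palettes, i.i.d. Gaussian sensor noise (sd 3, clamped),
and a mid-gray scale bar of known physical length outside the silhouette.
Ground truth — masks, area, length, width, fat fraction, channel means,
colour ratio — is computed from the rendering stencils, so it is exact by
construction. The generator runs on an isolated random stream: identical
seeds give bit-identical images and global RNG state is untouched.

Default resolution is 25 px/cm, a deliberately scaled-down desk analogue
of a close-range high-resolution capture; the default noise and palettes
make fat and muscle separate by ≥ 40 gray levels, the regime the
thresholding contract targets. `generate_grade_panel()` draws per-grade
parameter targets at least 10% of the interval width inside every grading
band (the colour targets are achieved by solving the muscle red channel
from the fat/muscle mixture equation, with the muscle kept bright enough
that the background/tissue split remains the dominant bimodality), then
verifies each sample's ground truth grades unanimously to the intended
grade before accepting it.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real photographs: illumination gradients and
shadows, specular wet-surface reflections, fascia and blood-stain
artifacts, soft fat/lean boundary gradients, camera optics (vignetting,
lens distortion, demosaicing), JPEG compression, and biological marbling
texture (blobs are a visual, not histological, model). On such clean
images the pipeline recovers the stencils nearly exactly; real-world error
budgets will be dominated by capture conditions the generator idealizes
away.

## Validation statistics

* `grid_area()` implements S = (N1 + N2)·a²; `simulate_grid_count()`
  emulates the manual count on a mask, with the grid origin at the mask
  bounding-box corner (the manual protocol has no defined origin; tests
  use alignment-robust tolerances). Cell coverage is evaluated on pixel
  centers; the refinement property — grid area error shrinking toward the
  pixel-count area as `a` decreases — holds while cells span many pixels
  and degrades by quantisation as the cell size approaches the pixel
  pitch, which is why tests assert it for a = 2 → 1 → 0.5 cm at 20 px/cm.
* `gaussian_outlier_filter()` fits by moments (mean and sample SD — for
  the normal family the same estimates a distribution-fitting tool would
  give), removes points beyond `k`·sigma (default k = 2.5; no
  authoritative cutoff exists, so it is a parameter, not a claim), refits
  once, and refuses to discard more than half the data. A consequence of
  the sample-SD fit worth knowing: for n points the largest attainable
  standardized deviation is (n−1)/√n, so at n = 5 *no* point can exceed
  2.5σ and the filter is intentionally inert on such tiny samples; the
  planted-outlier regime it is meant for (dozens of measurements, gross
  errors many σ out) is what the tests exercise.
* `pearson_agreement()` reports r with the exact two-sided t-transform
  p-value on n − 2 degrees of freedom (small-n appropriate; no
  permutation). `grading_accuracy()` is the exact match ratio with
  confusion counts — 28 of 30 reports as 93.33%, by arithmetic.

## Problem sizes and runtime choices

The test suite renders 50 sweep samples (5–80% fat, 18 px/cm) for marbling
recovery, a fixed-seed 30-sample panel (six per grade, 25 px/cm) for
end-to-end recovery, grading accuracy and grid-paper agreement, 200 random
≤ 32×32 masks against a brute-force flood-fill oracle, 100 random
histograms against an exhaustive intermeans fixed-point scan, and 30
random images against a sort-based contrast oracle. These sizes keep the
full suite around half a minute on one CPU while leaving every tolerance
meaningfully exercised.

## Known limitations

* One cut per frame; no automatic detection of the scale reference
  (reference points come from the manifest or the generator).
* No colour management: the R/(R+G+B) ratio is device- and
  illumination-dependent by design, which is acceptable only under a
  standardized capture protocol; no CIELAB conversion is provided.
* The marbling threshold of the original interactive workflow was tuned by
  eye and never printed, so exact mask replication is impossible; the
  deterministic intermeans surrogate (plus the explicit-threshold
  override) is the reproducible stand-in.
* Grading reflects the fixed interval table; no sensory-panel modelling,
  no physiological maturity or fat-colour scoring, and calibration
  uncertainty of the pixel scale is reported upstream, not modelled.
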