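---
title: "Evaluating nucleus instance segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating nucleus instance segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleval)
```

`nucleval` evaluates instance segmentations of cell nuclei at the object
level, generates synthetic microscopy images with exact ground truth, and
provides a configuration-free classical segmenter as a reference method.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The evaluation model

A segmentation is a *label mask*: an integer image in which 0 is background
and each positive integer is one nucleus instance. Given a target mask and
a predicted mask of the same image, every (target, prediction) object pair
receives an intersection-over-union score
$\mathrm{IoU}(A,B) = |A \cap B| / |A \cup B|$, computed sparsely (only
co-occurring label pairs are enumerated, which is exactly equivalent to the
dense all-pairs computation because a pair sharing no pixel has IoU 0).

At an IoU threshold $t$, objects are matched one-to-one over the pairs with
$\mathrm{IoU} > t$. The matcher takes pairs greedily in descending IoU
(ties broken by lower target label, then lower prediction label) and then
runs augmenting paths so that its cardinality always equals the maximum
one-to-one matching. The augmentation step matters only below $t = 0.5$:
above 0.5 at most one partner can exceed the threshold per object
(pigeonhole on pixel counts), so the greedy pass is already the unique
maximal matching, but at low thresholds conflict chains exist in which pure
greedy strands a match. Matched pairs are true positives TP($t$);
unmatched predictions are FP($t$); unmatched targets are FN($t$).
Object-level true negatives are undefined and carried as the constant 0.

Per threshold the package reports
$P = \mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$,
$R = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
$F1 = 2\mathrm{TP}/(2\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, and the
competition score averages the Jaccard-style term over the threshold grid:

$$S = \frac{1}{|T|}\sum_{t \in T}
\frac{\mathrm{TP}(t)}{\mathrm{TP}(t)+\mathrm{FP}(t)+\mathrm{FN}(t)},
\qquad T = \{0.10, 0.15, \ldots, 0.95\}.$$

### Numerical conventions

* **Strict inequality.** A hit requires $\mathrm{IoU} > t$, not $\ge t$.
  The convention matches the archived challenge implementation and makes
  the boundary case IoU = 0.5 well defined (it fails at $t = 0.5$); an
  `inclusive` flag is exposed for sensitivity checks.
* **Threshold grid.** $T$ is generated in integer hundredths
  (`seq(10L, 95L, 5L) / 100`), so the 18 values carry no floating-point
  drift and `parse_thresholds("0.10:0.95:0.05")` reproduces them exactly.
* **Empty-image conventions.** Any quotient with a zero denominator is 0,
  except the all-empty case TP = FP = FN = 0 (an image with no nuclei and
  no predictions), where P, R, F1 and the score term are all 1: a correct
  "nothing to find" answer is not penalized. With pooled percentages, a
  pool with no targets reports recall 100 / missed 0 and a pool with no
  predictions reports extra 0, so recall + missed = 100 holds identically.
* **Dataset aggregation.** S and F1 are computed per image and averaged
  unweighted across images (the challenge scored per image); the
  recall/missed/extra percentages at 0.7 IoU pool object counts over all
  images, because they describe fractions of objects, not of images. Both
  conventions are also available pooled (`pool_score = TRUE`). "Extra at
  0.7" is normalized by the pooled predicted-object count — the
  prediction-side analogue of missed — so it does not sum to 100 with
  recall; this is a documented choice where the convention is not pinned
  down by the metric's name.

## The synthetic image generator

The generator exists so that every other component can be exercised with
known ground truth and no external data. It emulates the five visual
groups of the challenge dataset — small fluorescent (bright ~12 px nuclei
on dark background), large fluorescent (~40 px), purple tissue (purple
nuclei on white), pink-and-purple tissue (purple nuclei on pink) and
grayscale tissue (dark nuclei on bright, colorless) — and the dataset's
group imbalance. The default mixture fixes the documented extremes (80%
small fluorescent, 0.6% for the rarest group, here large fluorescent); the
three middle proportions (9.0%, 6.4%, 4.0%) are package defaults chosen
once to fill the remainder in decreasing order of visual prevalence.

Each nucleus is an ellipse (aspect ratio 0.7–1) whose radius is modulated
by three low-order random harmonics; the `irregularity` parameter (0–1)
scales the total modulation and defaults higher for tissue groups, whose
nuclei are visibly more irregular. Equivalent diameters are drawn from a
normal distribution truncated at ±2.5 sd — a size prior implies bounded
sizes, and truncation keeps every generated nucleus inside the
segmenter's per-group diameter range. Objects are placed sequentially;
with probability `touching_prob` a nucleus is placed *adjacent* to an
existing one: its center is set at the anchor's measured boundary extent
along the placement direction plus the new radius (×0.92–1.02), so the
outlines touch or slightly overlap, and the overlap is carved away from
the later object. Non-touching placements enforce a 2 px gap. A placement
that loses more than 40% of its pixels to carving is retried; after 200
failed attempts generation stops with an error naming the constraint.

Rendering is deliberately simple: fluorescent nuclei are flat patches of
per-object brightness (0.60–0.95) on a 0.06 background in one channel;
tissue nuclei multiply a fixed background color by a fixed nucleus tint
(per-object jitter ×0.85–1.1) in three channels — a two-color stain model,
not an optical-density deconvolution. Optional degradations: a linear
illumination ramp, additive Gaussian noise, and Poisson-like shot noise
approximated by intensity-scaled Gaussian noise. Grayscale-tissue images
share one noise realization across channels, as a grayscale camera would.
The ground-truth mask is exactly the set of rendered supports *before*
noise; with `noise_sd = 0` and no touching, foreground and background
intensity distributions are disjoint by construction.

What this generator does **not** emulate — texture inside nuclei,
out-of-focus light, stain variation within an image, imaging artifacts,
overlapping (not merely touching) nuclei — bounds what passing tests show:
they validate the evaluation arithmetic and the pipeline's logic, not
performance on real microscopy.

All outputs are pure functions of the spec, including its seed; dataset
generation derives per-image seeds from the master seed by a fixed affine
map modulo a 31-bit prime, and per-group counts by largest-remainder
rounding with ties broken in group-name order.

## The classical reference segmenter

`segment_nuclei()` takes only an image — all parameters are fixed
per-group presets chosen at build time, mirroring the no-human-interaction
constraint a reference method should satisfy.

1. **Group classification.** A decision tree over the cues that define the
   groups: color vs grayscale by inter-channel variance (> 1e-4);
   fluorescent vs tissue by background polarity (median luminance < 0.5 →
   dark background → fluorescent); fluorescent small vs large by the median
   equivalent diameter of rough Otsu objects against a fixed 24 px cut;
   bright-background images split into grayscale tissue (colorless),
   purple tissue (near-white background) or pink-and-purple tissue
   (background saturation > 0.08). A constant image cannot be classified
   and falls back to small fluorescent at the lowest confidence.
2. **Foreground transform.** Luminance, inverted for tissue so nuclei are
   bright; the `stain_contrast` variant normalizes each channel to full
   range before inversion (no stain matrix is assumed). Gaussian smoothing
   at the preset sigma (1 px, 2 px for large fluorescent), rescaled to
   [0, 1]; a constant image stays constant.
3. **Primary objects.** Global Otsu threshold (the canonical
   parameter-free choice); the grayscale-tissue preset flattens the
   background first by subtracting a large-sigma Gaussian estimate
   (adaptive variant, for low contrast). Holes are filled. Declumping
   splits touching nuclei by watershed over the Euclidean distance
   transform: seeds are distance-map maxima within a neighborhood of
   `seed_min_distance / 2`, and maxima separated by a saddle shallower
   than 0.5 px of distance merge into one seed. The tolerance form was
   chosen over literal minimum-distance peak suppression because
   suppression discards the weaker peak of an unequal touching pair
   outright (the smoothed distance dome of a large nucleus can exceed a
   small neighbor's peak at its own location); a saddle-depth criterion
   expresses the same "one seed per nucleus" intent robustly. Objects
   with equivalent diameter outside the preset `[min_diameter,
   max_diameter]` are removed.
4. **Refinement.** The image is re-thresholded, the foreground is the
   union of that mask and the primary objects, and every foreground pixel
   is reassigned by seeded region growing from the primary objects over
   the intensity landscape. Each seed yields at most one output object, so
   refinement can recover eroded boundaries or remove objects (via the
   size prior) but never splits; when the primary stage already explains
   the thresholded foreground, refinement is a no-op.

Border-touching objects are kept (the evaluation counts border nuclei as
targets), watershed connectivity is 8-connected, and distance transforms
are Euclidean. Per-group presets: diameters 5–30 px (small fluorescent),
15–90 (large fluorescent), 5–32 / 6–38 (purple / pink-purple tissue),
5–28 (grayscale tissue); `seed_min_distance` defaults to roughly half the
group's minimum typical diameter.

## Observer agreement

`pairwise_agreement()` matches two segmentations of one image with the
same matcher at threshold 0 (any strictly positive overlap qualifies), so
boundary-noise comparisons retain weakly overlapping objects; the
per-object IoU distribution and its median summarize overlap agreement,
and F1 at the fixed 0.7 IoU threshold summarizes detection agreement. The
matched-IoU multiset is symmetric in the two arguments. When nothing
matches, the median is 1 if both masks are empty and 0 otherwise. Pooled
medians across images concatenate the per-object IoU lists
(object-weighted) rather than averaging per-image medians, matching how
per-object point clouds are usually displayed. No consensus mask or
annotator-bias model is attempted.

## Mask interchange

Run-length encoding uses the archived submission dialect: pixels numbered
1-based, top-to-bottom then left-to-right (column-major — R's native
order), `start length` pairs separated by spaces, one CSV row per object,
and a blank `EncodedPixels` field for an image with zero predictions.
Label masks read from disk may use arbitrary ids; they are relabeled to
`1..n` in ascending original-id order, and a label's pixels are not
required to be connected (no connectivity check is imposed — splitting
would silently change object counts). Overlaps in per-object inputs are
either an error (default) or resolved first-wins; both policies are
exposed because official annotation masks do not document a resolution
rule. Written label PNGs are plain 8-bit grayscale up to 255 objects and
24-bit RGB-packed beyond; both round-trip exactly.

## Problem sizes and determinism in the test suite

The suite validates the matcher against an exhaustive maximum-matching
oracle on all target/prediction count pairs up to 6×6 (three seeded
geometries each) plus 200 further seeded cases at every default threshold;
RLE round-trips on 1,000 seeded 32×32 masks; identity metrics on 50
synthetic images; clean-recovery of the segmenter on 100 noise-free
well-separated fluorescent images (20 nuclei each, exact object count and
pooled F1 = 1 at 0.5 IoU); and a 100-image five-group mixture at default
noise (pooled F1 ≥ 0.9 at 0.5 IoU). These sizes keep the default test run
around a minute on one core while exercising every code path; all
randomness is seeded, so failures reproduce exactly.

## Known limitations

* The segmenter's presets target the synthetic appearance models; on real
  stained tissue, stain variation and texture will degrade the simple
  inversion-based transform well before the watershed logic.
* Declumping is shape-based; truly overlapping nuclei (not just touching)
  are out of scope for both the generator and the segmenter.
* The agreement module quantifies disagreement but deliberately does not
  model annotator bias or build consensus masks.
* Boundary-distance metrics (Hausdorff, boundary F1) and panoptic quality
  are out of scope; the package implements the IoU-threshold family only.
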