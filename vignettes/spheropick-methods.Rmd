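---
title: "Methods: synthetic brightfield spheroid screening, from pixels to picks"
author: "spheropick maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic brightfield spheroid screening, from pixels to picks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheropick)
```

## What this package models

Tumour spheroids — self-assembled, roughly spherical aggregates of a few
hundred cells — are a standard 3D culture model, and downstream assays want
*similar* spheroids: a narrow size band and a rounded shape. Picking them by
hand under a stereomicroscope is slow and noisy. An automated
screen-and-transfer instrument images wells in brightfield, segments
spheroid instances, measures their morphology in physical units, selects
the ones that meet user criteria, and moves each selected spheroid to a
target well with a capillary and syringe pump.

`spheropick` implements the computational core of that workflow end to end,
with a synthetic scene generator standing in for the microscope so that
every stage can be exercised against exact ground truth:

1. **fixtures** — seeded synthetic brightfield scenes with exact instance
   masks;
2. **segmentation** — classical Otsu and watershed pipelines, shape-based
   object filters, the 1024 x 1024 resize/pad preprocessing, and a
   registry where learned segmenters can plug in;
3. **morphometrics** — per-object area, perimeter, circularity, equivalent
   diameter, solidity and volume in micrometre units;
4. **selection** — interval criteria, preferred-value ranking and
   population summaries;
5. **evaluation** — IoU-matched detection precision/sensitivity across a
   threshold grid;
6. **platform** — plate geometry, image-to-stage calibration, scan tiling,
   transfer planning and Marlin-dialect G-code emission;
7. **pipeline** — dataset splitting and an end-to-end runner with a
   structured run log.

## The synthetic scene model

A scene is a bright background (default intensity 0.75 of dynamic range)
with an optional centred linear illumination gradient. Each spheroid is a
star-shaped region whose boundary is a truncated Fourier perturbation of a
circle,

$$ r(\theta) = R\,\bigl(1 + \textstyle\sum_k a_k \cos(k\theta + \phi_k)\bigr),
   \qquad k \ge 2,\; a_k \in [0, 0.3),\; \sum_k |a_k| < 0.5, $$

rendered by a per-pixel inside-curve test. The amplitude bounds guarantee a
simple closed boundary containing the centre, so the ground-truth mask is
always one 8-connected component. The interior is darker than the local
background (default 0.5x), ringed by a thin bright halo (default 1.1x
background over 3 px) — the classic brightfield appearance of a dense cell
aggregate. Optional per-object Gaussian defocus blurs the object's
*contribution* before compositing; additive Gaussian sensor noise is drawn
last from the scene's seeded generator, so noise is applied after blur as
on a real camera. Identical `SceneSpec`s render bit-identically.

Artifacts perturb the image but never the mask:

* **air bubbles** — dark annular *arcs* (open rings, 200-315 degrees);
* **plate borders** — large-radius dark arcs sweeping through a corner of
  the field, as a curved well edge does;
* **plastic defects** — thin dark zig-zag streaks.

All three were chosen to reproduce the characteristic failure modes of
intensity-threshold pipelines: they are dark enough to cross a global
threshold, yet geometrically unlike a spheroid. They are deliberately
rendered as *open* or *bent* shapes. A closed annulus would be filled solid
by the hole-filling step every threshold pipeline applies and would come
out with solidity near 1; an open arc survives hole filling and keeps the
low solidity that makes the `minSolidity` filter effective against it. This
matches practice: bubble and border edges rarely close into a full ring
inside one field of view.

### Study conditions

The benchmark profiles fix the generator's conditions. Scenes are 512 x 512
px at 2.0 um/px (a realistic stereomicroscope sampling; the true camera
calibration of such instruments varies and is configurable everywhere),
with 1-5 spheroids per scene and equivalent diameters drawn uniformly from
200-250 um — the size band such cultures are grown to. The `round` profile
(perfect disks, no artifacts) provides morphometric ground truth; `clean`
adds mild boundary irregularity (amplitudes to 0.05); `default` adds
defocus to 3 px, stronger irregularity (to 0.12), 2% noise and occasional
artifacts; `artifact` guarantees 1-3 artifacts per scene. Problem sizes in
the test-suite and acceptance runs (tens of images per profile) keep a full
run in the order of a minute while still pooling 50-150 objects per
estimate.

What passing these tests does *not* show: the generator has no texture
inside objects, no uneven in-well shading beyond a linear ramp, no touching
*overlapping* spheroids (overlap is rejected; real aggregates can fuse),
and artifacts are geometric idealizations. Results on the synthetic
profiles bound what the classical pipelines can do under controlled
conditions; they do not predict absolute performance on real imagery.

## Segmentation

`segmentOtsu()` smooths with a Gaussian (sigma 2 px by default — it
stabilizes the global threshold under sensor noise), takes the global Otsu
threshold, keeps the darker side (brightfield polarity, invertible by
flag), fills holes, labels 8-connected components, and applies the object
filters. `segmentWatershed()` shares the foreground step, then splits it by
a watershed on the distance transform seeded at distance maxima; the
minimum seed separation (default 10 px) controls over-splitting.
Connectivity is 8-connected throughout, the common choice in blob analysis.

Preprocessing for external (learned) backends follows the standard recipe:
scale by `1024 / max(h, w)` (bilinear), anchor top-left, zero-pad right and
bottom to 1024 x 1024. The anchor is a free choice — nothing downstream
depends on it — and top-left makes the inverse map trivial. Masks travel
back through `unmapMask()` with nearest-neighbour interpolation so label
identities survive. Images are interpolated bilinearly, masks never are.

Default filter bounds are permissive on purpose: the right area band
depends on magnification, and the shape bounds are the operator's decision.
The filters are exactly idempotent.

## Morphometrics

Area is pixel count times the squared pixel size. The perimeter is a
Crofton 4-direction estimate (intercept counts in four directions combined
with the Cauchy-Crofton coefficients). The choice matters: counting
boundary pixels overestimates the perimeter of a digital circle by ~5%,
which would push the circularity

$$ C = \frac{4\pi A}{P^2} $$

of a true circle down to ~0.9 and make a threshold like "circularity at
least 0.815" meaningless. With the Crofton estimate a digital disk of
radius 50 px scores C = 0.992, so the threshold discriminates the way an
operator expects. Circularity is clamped at 1.

Solidity is pixel area over the rasterized convex-hull area (hull through
pixel centres, counted on the pixel grid; degenerate hulls score 1).
Equivalent diameter is $2\sqrt{A/\pi}$ — the 25,000 um^2 reference area
corresponds to 178.41 um. Volume is the sphere of equal equivalent
diameter, $(\pi/6)\,d_{eq}^3$; the method is recorded as
`"sphere_equivalent"` in the table attributes since it is a single-view
estimate that assumes near-sphericity. All features are scale-equivariant:
doubling the pixel size quadruples areas, doubles perimeters, and leaves
circularity and solidity unchanged.

Coordinates are (row, col), 1-based at pixel centres, with stage x along
columns and y along rows.

## Selection

Criteria are closed intervals per feature, inclusive at both ends — an
object with circularity exactly 0.815 passes a "minimum 0.815" criterion.
Rejection reports the *first* failed criterion in a fixed order (area,
circularity, then remaining features alphabetically) so logs are
reproducible. With a preferred target value the selected set is ranked by
absolute distance, ties broken by ascending label; a cap applies after
ranking. Without a preferred value, scan order is kept — the natural order
in which an instrument would offer objects. Summaries use the sample
standard deviation (n-1); a single value reports sd 0 with an explicit
`sdDefined = FALSE` flag.

One caution when chaining defaults: the generator grows spheroids to
200-250 um diameter (31,400-49,100 um^2), while the classic selection
window 21,000-29,000 um^2 corresponds to 163-192 um diameters. Applied to
the generator's default population that window selects nothing — the two
defaults describe different experimental stages (growth vs. transfer of
the smaller, rounder fraction), so selection demonstrations here use
feature populations centred on the 25,000 um^2 target.

## Evaluation

The detection score is deliberately the strict form

$$ P = \frac{TP}{TP + FP + FN}, \qquad S = \frac{TP}{\text{Positive}}, $$

which penalizes both spurious and missed objects; the classical precision
$TP/(TP+FP)$ is emitted alongside under `classical_precision` for
comparison with other tools. Matching is the exact maximum-total-IoU
one-to-one assignment over pairs with IoU at or above the threshold,
computed by bitmask dynamic programming over the smaller side of the IoU
matrix (at most 14 objects; beyond that a greedy descending-IoU fallback is
used, which is provably identical above IoU 0.5 where matches are mutually
exclusive). Exactness is tested against exhaustive search over all
one-to-one matchings.

Aggregation over a dataset is *pooled* (micro) by default: counts are
summed per threshold and scored once. Per-image averaging is available;
images without ground-truth objects are excluded from the sensitivity
average and score P = 1 when the prediction is also empty. The default
threshold grid is 0.50 to 0.95 in steps of 0.05.

## Virtual instrument

Plate geometry follows ANSI/SLAS conventions (96-well: 9 mm pitch, A1 at
(14.38, 11.24) mm; 384-well: 4.5 mm; 24-well: 19.3 mm), overridable per
layout. Calibration reduces to one registered tip pixel, a pixel size and
two axis signs; `imageToStage()` is the affine map from image displacement
to stage displacement and `stageToImage()` its inverse (round trip within
half a pixel). Scan plans tile each well's bounding square with fields
stepped by `fov * (1 - overlap)` in serpentine order, which minimizes stage
travel; the tile count per axis is `ceil((side - fov) / step) + 1`, so
coverage is guaranteed by construction.

Transfer plans emit, per spheroid: stage move to the source, pipette over,
down to the safe floor, aspirate, up, stage move to the target well, down,
dispense, up — and a final pipette retraction out of the field. Plan
validity enforces exactly one aspirate before one dispense per spheroid,
no pipette motion below the safe height, and aspiration volumes within
bounds (default 3-4 ul, default volume 3.5 ul — the midpoint of the small
fluid plug that reliably carries one spheroid without grabbing a second).
G-code is Marlin dialect: pipette X/Z as `G1` moves, the syringe pump as
extruder moves with negative E for intake, and stage motions as structured
comments, because the stage sits on a separate controller and inventing a
protocol for it would be fiction. Success statistics tally the four
transfer outcomes (success, pick-up error, expel error, double pick) and
round the success rate to the nearest integer percent.

## Numerical choices and degenerate inputs

* Blank or constant images segment to an empty mask rather than erroring.
* `tp = fp = fn = 0` scores detection precision 1 by convention;
  sensitivity is undefined (error) without ground-truth objects.
* Interval bounds, filter bounds and matching thresholds are inclusive.
* JSON round-trips of scene specifications carry ~15-16 significant
  digits; masks survive exactly, intensities to within one part in 1e9.
* Dataset splitting shuffles with the given seed, then assigns
  contiguously with largest-remainder rounding (ties resolved train, val,
  test), per image — objects inherit their image's split, so no object
  population leaks across sets.
* All library-internal randomness is scoped: the caller's RNG state is
  saved and restored.

## Known limitations

The generator's optics are deliberately simple (no PSF model beyond
Gaussian blur, no vignetting). The classical pipelines here are reference
baselines — the registry exists precisely because learned models outperform
them on hard conditions; training such models is out of scope. Volume from
a single view is biased for non-spherical aggregates. The G-code dialect
targets Marlin-style firmware; other controllers need a different emitter.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(
  stages = c("simulate", "segment", "features", "evaluate"),
  seed = 1,
  simulate = list(n = 10, profile = "clean"),
  segment = list(method = "otsu", filters = list(minAreaPx = 50)),
  evaluate = list(taus = seq(0.5, 0.95, by = 0.05)))
res <- runPipeline(cfg, "run1")
curveData(res$curve)
```

The run directory then holds the rendered scenes, ground-truth masks,
predictions, the feature table, the evaluation curve and a JSON-lines run
log with seeds and timings — enough to reproduce or audit every number.
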