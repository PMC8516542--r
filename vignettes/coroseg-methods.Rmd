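---
title: "Vessel enhancement, segmentation and tracking: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel enhancement, segmentation and tracking: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coroseg)
```

`coroseg` extracts the vascular tree from 2D X-ray coronary angiograms:
dark, curvilinear, branching vessels on a bright, noisy, unevenly
illuminated background. The pipeline is

1. **preprocessing** — collaborative block-matching denoising, unsharp
   masking, CLAHE;
2. **multiscale Hessian vesselness** — per-pixel tube-likeness, the
   enhanced image all later stages operate on;
3. **Chan–Vese level-set segmentation** — the binary vessel mask and
   sub-pixel contour;
4. **ridge detection** — candidate centerline pixels;
5. **adaptive tracking** — arc-search stepping from a seed ridge point,
   contour-based center adjustment, fan-ring bifurcation detection.

Validation is phantom-driven: `renderPhantom()` draws synthetic tubular
trees with exact ground truth, and `centerlineError()` /
`bifurcationScore()` measure recovery. This document records the models,
their assumptions, and every numerical decision that was genuinely open.

## Coordinates and polarity

Pixels are indexed `x` = column, `y` = row, both 0-based, with pixel
centers at integer coordinates; angles are in degrees from the +x axis,
increasing toward +y (image convention, y down). Coronary vessels are
dark; with `vessel_polarity = "dark"` (the default) the preprocessed
image is inverted (`255 - I`) before enhancement, so that the vesselness
function (which responds to *bright* tubes) applies as written and the
tracker's gray-maximum searches are well defined.

## Preprocessing

**Denoising** (`denoiseImage()`) is a simplified two-stage collaborative
filter: image blocks on a half-block-stride grid are matched by L2
distance inside a search window, hard-thresholded in the 2D DCT domain
(threshold 2.7 sigma), averaged across each matched group, and
aggregated over overlaps with weights proportional to the inverse
retained-coefficient count. Defaults: `noise_sigma` 10 (on the [0, 255]
scale), 8 px blocks, 16 px search window, groups of up to 8. The
contract is contrast preservation on constants, bit-identity at
`noise_sigma = 0`, and substantial MSE reduction on piecewise-constant
scenes — not bit-compatibility with any particular reference binary.

**Unsharp masking** (`unsharpMask()`) adds back the high-frequency
residual, `g = I + k (I - lowpass(I))`, with a mean filter (default
9 px, replicate borders) as the low-pass and `k = 1.5`. The operator is
exactly linear before the final clip to [0, 255].

**CLAHE** (`clahe()`) equalizes per tile (8 x 8 tiles, 256 bins) with
the histogram clipped at 2.5 x the uniform bin height; clipped mass is
redistributed equally over all bins, iterating (at most 16 times)
because redistribution can push bins back over the limit. Pixels are
mapped by bilinear interpolation between the CDF mappings of the four
surrounding tile centers.

## Multiscale vesselness

For ordered Hessian eigenvalues `|lambda1| <= |lambda2|` the
tube-similarity is zero when `lambda2 >= 0` and otherwise

    V = exp(-RB^2 / (2 beta^2)) * exp(-2 m^2 / lambda2^2)
        * (1 - exp(-SH^2 / (2 c^2)))

with blobness `RB = |lambda1| / |lambda2|` and structureness
`SH = sqrt(lambda1^2 + lambda2^2)`. Defaults `beta = 0.5`, `c = 20`,
scales `sigma = 1..10` (10 integer scales). The middle factor is
implemented exactly as written; its exponent does not reduce to the
usual two-factor form for any `m > 0`, so the default is `m = 0`, which
makes it identically 1.

Each scale uses Gaussian smoothing followed by central second
differences, multiplied by `sigma^gamma` with `gamma = 2`
(scale-normalized derivatives); without this normalization the
across-scale maximum would be meaningless. The per-pixel winner's scale,
eigenvalues, along-vessel eigenvector and smoothed-image gradient are
kept in the returned `VesselnessMap`, because the ridge detector and the
tracker consume them. The response is min–max rescaled to [0, 255].

Two properties of this enhancement matter downstream. First, the
response of an isolated blob is an *annulus* per scale (at that scale's
inflection radius), not a peak — Hessian filters are tube detectors, and
their blob response is genuinely ring-shaped. Second, near a
bifurcation the response dips (blobness rises) and the two branches'
responses fuse into one wide ridge until they are a couple of widths
apart; this merge zone is what limits junction localization below.

## Chan–Vese segmentation

The two-phase piecewise-constant energy

    F = u L(C) + v S(C) + lambda0 ∫ (I - c0)^2 (1 - H(w))
                        + lambdab ∫ (I - cb)^2 H(w)

is minimized over a level-set field `w` (positive inside) with the
arctangent-regularized Heaviside (`epsilon = 1.5` px). Defaults:
`u = 0.2 * 255^2`, `v = 0`, `lambda0 = lambdab = 1`, `dt = 0.5`,
500 iterations, signed-distance reinitialization every 50.

The update is an explicit descent of this energy with three deliberate
numerical choices, each adopted after the plain regularized
Euler–Lagrange step demonstrably failed on enhanced vessel images:

* **Intensity normalization.** The energy is invariant under jointly
  rescaling intensities to [0, 1] and the weights by 255^2, so the
  descent runs on the normalized problem. On the raw scale the fit
  forces (~255^2) overwhelm any fixed step; the normalized step is
  stable at `dt = 0.5`.
* **Global fit forcing.** The regularized delta multiplies only the
  geometric (length/area) terms; the fit forcing acts on all level sets.
  This is the classic global-minimization variant of the model — a
  diagonally preconditioned descent of the same energy. With the fully
  delta-localized update, pixels away from the contour are frozen and
  the evolution converges to whatever partition the initialization
  dictates; on the Y-tree response the frozen partition's energy was
  measured at 4.0e7 against 1.9e7 for the partition the global variant
  reaches.
* **Sharp region means.** Inside the evolution, `c0`/`cb` are computed
  over the sharp partition `{w > 0}`. The H-weighted means mix
  near-contour pixels of the other phase into each average; for
  structures only a few `epsilon` wide — exactly the vessels this
  package targets — that bias was measured at ~40% of the inside mean.
  The exported `regionMeans()`/`cvEnergy()` keep the regularized
  definitions for energy reporting.

**Initialization.** Two kinds are provided: a `sin(pi x / p) sin(pi y /
p)` checkerboard and a signed-distance circle. The pipeline default is a
small circle (radius 5) seeded at the brightest pixel: on a sparse
enhanced image the mean-based partition has multiple fixed points, and
an initialization whose inside mean starts high lands in the good basin
(the checkerboard starts both means at the global mean and converges to
a low-threshold, over-inclusive partition). On images whose two phases
both carry mass (the disk benchmarks), both inits converge to the same
partition.

**Labeling.** With `v = 0` and `lambda0 = lambdab` the energy is
invariant to swapping inside/outside, so the sign of `w` is
canonicalized to make the inside the brighter phase. Consequently the
returned partition is init-independent and polarity inversion flips only
the labels.

**Energy history and stopping.** The recorded history is the regularized
energy evaluated before each reinitialization; reinitialization rebuilds
`w` as a signed distance to the *same* contour, which re-expresses the
regularized terms, so the history is non-increasing *within* each
reinitialization window (that is the property the tests assert).
Stopping: relative energy change below `tol = 1e-5` for five consecutive
iterations, or `max_iter`. Constant images short-circuit to an empty
mask with a warning. Contours are extracted from the zero level by
marching squares with linear interpolation, closed through a padded
negative frame at the borders.

## Ridge detection

A ridge point approximates a local maximum transverse to the vessel on
the enhanced image. Per pixel, at its winning scale:

* **sign change** — the dot product of the gradient vectors across
  either diagonal of the pixel cell is negative (with a relative
  deadband of 1e-6 of the maximal gradient against FFT round-off), *or*
  the transverse derivative `g . v2` is numerically zero — the exact
  on-ridge case, which the strict product test misses because the
  product is 0, not negative, when the centerline sits on a pixel row;
* **curvature** — `lambda2 < 0` at all four cell corners, with the
  blobness cap `|lambda1| / |lambda2| < 0.25`. The along-vessel
  eigenvalue of an ideal tube is exactly zero and its sign is
  uninformative: requiring `lambda1 < 0` erased ~20 px of centerline
  wherever a neighboring branch's skirt creates a shallow along-vessel
  saddle (just past every junction), which in turn starved the
  bifurcation search. The cap performs the line-vs-blob discrimination
  that condition was standing in for, on the same `RB` scale the
  enhancement's `beta` uses;
* **screening** — response above `gray_threshold` (default 10, the
  tracker's intensity floor, keeping a single intensity floor across
  modules).

The scattered-point prefilter removes P when fewer than `tau_R = 3`
other ridge points lie within `radius` (single pass against the input
set, so the result is a subset but the operation is not idempotent).
The radius default is 3.0 px: an oblique single-pixel chain has sample
spacing sqrt(2), and a radius of 2 gives its interior points only two
neighbors — the filter would erase whole diagonal segments of thin
vessels instead of isolated speckle.

## Adaptive tracking

From a seed ridge point, the forward point is the gray maximum on the
circle of radius `d = 5`; the backward point is the maximum on the arc
of half-angle 45 degrees centered on the direction *opposite* the
forward one (the reflection `360 - theta` that a literal reading
suggests retraces the forward direction for horizontal vessels).
Stepping searches the arc of radius `d` and half-angle
`delta_theta = 45` around the current direction (1-degree sampling,
bilinear interpolation; ties prefer the smaller angular offset), and a
candidate is accepted iff its intensity exceeds `I0 = 10` and fewer than
`tau_P = 4` previously accepted points lie within `np_radius = d` (the
loop guard). The direction update uses the forward difference
`u_k = (P_k - P_{k-1}) / ||.||`.

**Center adjustment** casts rays along both perpendiculars of the
current direction (0.25 px steps, up to `max_ray = 20`), interpolates
the two mask exits and moves the point to the chord midpoint,
re-aiming the direction from the previous point. Adjustment is applied
at every step, but a displacement cap (`max_shift = 2` px) rejects
corrections larger than a drift plausibly is: at a fused junction the
normal chord spans both vessels and its midpoint otherwise teleports
the track into the other branch's fairway (measured: an entire trunk
lost from one seed). Failed or capped adjustments leave the state
unchanged, flagged.

**Bifurcation detection** searches, at every accepted point, the fan
ring of radii `(r1, r2) = (7, 12)` and half-angle 135 degrees around
the current direction for ridge points whose bearing differs from the
current and previous directions by more than `tau1 = 45` /
`tau2 = 30` degrees, farther than `d`, with fewer than `tau_B = 2`
recorded bifurcations within `nb_radius = r2`. The qualifying candidate
of maximal enhanced intensity seeds a new branch (tracked FIFO, away
from its parent); the *tracking point at which the branch was found* is
recorded as the bifurcation location — it lies on the parent vessel
next to the junction, whereas the candidate ridge point necessarily
lies `r1` or more away along the new branch.

**Known limitation — junction localization.** The fan ring's inner
radius and backward exclusion mean no qualifying candidate exists until
the track is past the junction, and the response merge zone delays the
first usable candidate further; recorded bifurcations land ~9–20 px
downstream of the true junction on a 40-degree Y at the default
parameters, and a 40-degree branch sits right at the `tau1 = 45`
detection threshold. Branch *recovery* (coverage) is unaffected — the
queued branch covers the missed segment from the other side — but
junction *positions* should be read with a ~2 x `d` uncertainty. The
acceptance suite asserts a 5 px tolerance for this quantity and is
expected to flag it.

## Phantoms and metrics

`phantomSpec()` branches are quadratic Bezier curves with a Gaussian
cross-section (`sigma = halfwidth / 2`, so the nominal edge at one
halfwidth sits at `exp(-2)` of the peak), linear width taper, per-pixel
maximum composition, optional linear illumination gradient and seeded
additive Gaussian noise. Ground truth (dense 0.5 px centerlines, local
half-widths, junctions, the mask `{distance <= halfwidth}`) is computed
from the curves, not from the rendering. The stock phantoms are the
suite's study conditions: a straight tube (256 x 256, half-width 3,
contrast 120 over background 30), an S-shaped tube, a Y tree whose main
vessel continues straight with a side branch at 40 degrees (the reading
of "branch angle" consistent with a detectable side branch and with
coronary morphology), and the same Y tree dark, shaded (gradient -0.08
and +0.05 gray/px) and noisy (sigma 15), which exercises the full
preprocessing chain. What the phantoms do **not** emulate: X-ray
projection physics, cardiac motion blur, catheters, vessel overlap and
foreshortening, or spatially correlated noise — passing here shows the
algorithms implement their models correctly, not clinical performance.

`centerlineError()` reports the mean distance from tracking points to
the truth centerline; coverage is the fraction of truth points within
2 px of the skeleton *polyline* (branches interpolated at 0.5 px —
tracking points are spaced `d` apart, so point-to-point coverage would
be capped at `4/d` even for a perfect track). `bifurcationScore()`
merges detections within the tolerance into centroids, then matches
greedily one-to-one; no detections means precision 1.

Problem sizes used throughout the tests: 256 x 256 phantoms, 128 x 128
disks, 500 level-set iterations — small enough to iterate on quickly,
large enough that every operator runs in its asymptotic regime.

## Determinism

All randomness (seed selection, phantom noise) flows from explicit
integer seeds and is restored-RNG-safe; skeleton JSON is written with a
fixed 6-decimal format, so identical inputs and seeds give
byte-identical outputs.
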