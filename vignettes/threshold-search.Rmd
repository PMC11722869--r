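---
title: "Threshold search for edge detection on noisy images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold search for edge detection on noisy images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgethresh)
```

## The procedure

`edgethresh` studies a simple but practically important question: when a
reference (ground-truth) edge map is available, how much does classical
edge detection improve if the detector threshold is *chosen against that
reference* rather than set automatically? The procedure is:

1. load an image and its ground-truth edge map;
2. build a dataset of candidate thresholds per operator;
3. detect edges at candidates chosen by grid search (GS, all candidates) or
   random search (RS-k, best of k seeded draws without replacement), scoring
   each detection with an objective measure (F, FoM or PR);
4. return the best-scoring edge map and its threshold.

The package exercises this under four noise models at fixed intensities,
across images of three complexity classes, against the automatic no-search
baseline (`standard_detect()`, Otsu's threshold on the operator response).

All images are represented on a normalized `[0, 1]` intensity scale (8-bit
input divided by 255), and every detector response is min–max normalized per
image, so a single (0, 1) threshold grid is meaningful for every operator
and image. This normalization is the key assumption that makes one
candidate dataset transferable across detectors.

## The candidate dataset

`generate_threshold_dataset()` places single-operator candidates on the
uniform grid t_i = i/(n+1), i = 1..n. Canny candidates are (low, high)
pairs on the same grid of highs with `low = 0.4 * high`, which keeps the
two-threshold operator on a one-dimensional, exhaustively searchable grid
while doubling its stored values. The default n = 300 stores
4·300 + 2·300 = 1800 values; a compact n = 100 preset (the pipeline
default) keeps full-grid experiments fast. The uniform grid is a design
choice — nothing in the method depends on the specific candidate values,
and datasets can be read from CSV instead.

Ties in either search break toward the smallest candidate (the candidate
list is scanned in ascending order and only a strictly better score
replaces the incumbent), making GS fully deterministic and RS deterministic
given its seed.

## Detectors and their numerical choices

* **Sobel/Prewitt/Roberts** — classical kernel pairs, applied in true
  convolution orientation with replicate (edge-clamp) borders; replicate
  padding avoids the spurious frame of edges that zero padding produces.
  Roberts operates on the 2×2 forward neighborhood anchored at the top-left
  pixel, with replicate padding for the last row/column. Detection marks
  pixels whose normalized magnitude strictly exceeds the threshold.
* **LoG** — Gaussian smoothing at σ = 2.0 px, 3×3 Laplacian, response
  normalized by its maximum absolute value; a pixel is an edge when an
  opposing 4-neighbor pair changes sign and the absolute response
  difference across the crossing exceeds the threshold. Using opposing
  neighbor pairs (rather than the pixel's own sign) matches classical
  zero-crossing implementations.
* **Canny** — smoothing at σ = 1.4 px (kernel truncated at 4σ and never
  wider than the image), Sobel gradient, non-maximum suppression with the
  gradient direction quantized to four sectors, double threshold on the
  normalized magnitude, and 8-connected hysteresis. On an exactly
  symmetric discrete step the two pixels straddling the boundary tie in
  magnitude; NMS keeps a pixel when it is strictly greater than its
  *previous* directional neighbor and at least equal to the *next*, which
  retains exactly one of the tied pair and yields 1-px lines on clean
  steps.
* **Standard baseline** — Otsu's threshold (256-bin between-class variance
  maximization) on the operator's normalized response values; for Canny,
  `high` is the Otsu value and `low = 0.4·high`. A completely flat response
  yields an empty edge map.

## Measures, conventions and matching tolerance

F, FoM (α = 1/9, `max(N_I, N_D)` normalization — the classical Pratt form)
and the bounded PR = tp/(tp+fp+fn) are all in `[0, 1]` and equal 1 exactly
on identical maps. Conventions for degenerate cases: both maps empty
scores 1 on every measure (the identity case stays a fixed point); exactly
one empty scores 0. PR is deliberately the bounded form — selection needs
a bounded, maximizable score; the unbounded tp/(fp+fn) variant is available
behind a flag.

Matching at `tolerance = 0` demands exact pixel coincidence. Discrete
boundaries make that a harsh criterion: an intensity step between columns
c and c+1 excites a first-derivative operator equally on both sides, while
the phantom ground truth is the 1-px interior boundary, so a structurally
perfect detection can be capped well below F = 1 by a one-pixel offset.
The metrics functions therefore default to exact matching (the only
assumption-free choice), while the search and pipeline default to
`tolerance = 1` px, which forgives one-pixel offsets but nothing more.
Distances are exact Euclidean (distance-transform based), so tolerance 1
covers the 4-neighborhood only.

## Noise models

Intensity semantics follow the `imnoise` family conventions: variance for
Gaussian and speckle, corruption density for salt-and-pepper. The speckle
multiplier is uniform on ±sqrt(3v) (the same convention; a Gaussian
multiplier is selectable). Rician noise is the standard magnitude-MRI
model sqrt((I+n₁)² + n₂²) with n₁, n₂ ~ N(0, σ²); its "intensity" is read
as σ, so the zero-signal limit is Rayleigh with mean σ·sqrt(π/2) — the
property the tests verify. All outputs are clipped to `[0, 1]` (required
by the image invariant; at the studied intensities on mid-gray images the
clipping bias is negligible except for Gaussian noise at variance 0.1,
where moments are compressed — the moment tests therefore pin the Gaussian
model at variance 0.01 and the others at all study intensities). Every
simulator takes an explicit per-call seed and restores the session RNG
state.

## Complexity classes

Spatial information is the per-pixel Sobel gradient magnitude; the package
reports its mean, *population* standard deviation and RMS. The population
convention makes `si_rms² = si_mean² + si_stdev²` an exact identity, and
"RMS" is the RMS of SI itself (there is no reference signal to take an
error against). Class boundaries (b₁, b₂) assign LD/MD/HD from the SI mean
with right-open intervals. Because no canonical boundary values exist for
synthetic imagery, `calibrate_boundaries()` uses corpus terciles (33.33rd
and 66.67th percentiles, linear interpolation) as the default calibration
and rejects degenerate corpora; fixed boundaries can be supplied instead.

## What the phantoms emulate — and what they do not

`make_phantom()` produces the three complexity regimes as structural
archetypes: LD = 1–3 large filled shapes; MD = 8–15 mixed shapes plus thin
smooth curves; HD = 30+ small shapes, a recursively bifurcating
vessel-like tree, and mild smooth texture (amplitude 0.02). Structures are
placed with ≥ 2 px clearance so every boundary is a clean
structure-versus-background step with ≥ 0.2 intensity contrast, and the
ground truth is the exact interior rasterized boundary (thin curves are
their own boundary), post-processed to contain no 2×2 solid block. The
generator is calibrated so mean SI orders the classes LD < MD < HD and so
tercile classification recovers the generated labels.

Phantoms deliberately target this SI ordering, not anatomical fidelity:
real medical images have textured interiors, blurred and low-contrast
boundaries, imaging artifacts, and ground truth drawn by humans (often
thick or subjective). Passing results on phantoms demonstrate the
correctness and internal consistency of the machinery — search dominance,
metric behavior, degradation with noise — not clinical performance.

## Experiment design

`run_experiment()` corrupts each image once per noise specification with a
sub-seed derived by hashing (master seed, image id, noise kind, intensity),
then runs every (operator, method) on the shared noisy image, so method
comparisons are paired and the whole grid reproduces from one master seed
without storing noisy images. Random-search cells likewise derive their
draw seeds per cell; each RS cell uses a single seeded draw (repetition is
a configuration choice). Default grid: Gaussian, salt-and-pepper and
speckle at intensities 0.01/0.05/0.1 and Rician at 0.05/0.1/0.15; all five
operators; standard, GS and RS9.

Desk-scale study sizes, used by the test suite and `scripts/acceptance.R`:
a 30-phantom corpus (10 per class) at 96×96 with the 100-value candidate
preset — 360 noisy images and 5400 detection cells, a few minutes on one
CPU. Threshold sweeps exploit monotonicity: a single-threshold detection
is `response > t`, so sweep scores are computed from pre-sorted response
values in O(log n) per candidate, with the winning map rebuilt through the
ordinary detection path; an equivalence test pins the sweep to the naive
detect-and-score loop.

## Known limitations

* GS cost grows linearly in dataset size and image area; Canny pairs
  re-run hysteresis per candidate.
* The Canny candidate grid ties low = 0.4·high; genuinely independent
  (low, high) grids would square the search space and are not the default.
* Tolerance-1 scoring is still stricter than the boundary-matching used by
  BSDS-style benchmarks (no optimal assignment, no ODS/OIS aggregation).
* Complexity boundaries calibrated on phantoms do not transfer to real
  corpora; recalibrate on the target corpus.
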