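---
title: "Estimating food weight from top-view photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating food weight from top-view photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodarea)
```

## The problem

Quantifying how much someone actually ate is the hard part of dietary
assessment. Scales are accurate but intrusive; self-report is neither.
`foodarea` implements the middle road: a single top-view photograph taken
at a known height with a known lens, from which the food's projected area
is measured in physical units and converted to weight through a per-trait
linear calibration. The package covers the full chain — camera geometry,
classical segmentation, calibration fitting, validation statistics — plus
a synthetic scene generator that stands in for a captured image corpus,
so every stage can be tested against exact ground truth.

## Camera geometry

### The model

A thin lens with focal length $f$ images an object at distance $u$ onto a
plane at distance $v$, with $1/v + 1/u = 1/f$ and magnification
$m = v/u = f/(u-f)$. A length $\ell$ on the image plane therefore
corresponds to $\ell\,(u-f)/f$ in the object plane. Sensor sizes vary
across phones, so all focal lengths are expressed as 35-mm equivalents:
the focal length a full-frame (36 × 24 mm) camera would need for the same
diagonal field of view. Under that convention a 4:3 image behaves as if it
were formed on the 4:3 rectangle sharing the full-frame diagonal
(43.27 mm), i.e. a 34.61 × 25.96 mm frame; `equivalent_frame()` derives
these numbers, and the package uses them at the conventional printed
precision 34.6 / 26.0 / 43.3 (and 36.0 for 3:2 width), which is what
sensor conversion tables state.

With $x$ pixels along the short axis of an $a$-pixel-wide 4:3 image, the
image-plane length is $26.0\,(x/a)$ mm, and the object length is

$$A = 26.0\,\frac{x}{a}\left(\frac{u}{f_{35}} - 0.1\right)\ \text{cm},$$

with the package-wide **unit convention: $u$ in cm, $f_{35}$ in mm,
results in cm/cm²**. The 0.1 in the bracket is exactly the cm/mm mixing
($u_\text{mm}/f - 1 = 10(u_\text{cm}/f) - 1$); no other unit assignment
reproduces it, which is how the convention was pinned down, and a test
asserts the identity against the thin-lens derivation to $10^{-9}$
relative over a dense $(u, f_{35})$ grid. An $n$-pixel region covers
$S = n\,[(26.0/a)(u/f_{35} - 0.1)]^2$ cm².

### Conventions and edge cases

* `width_px` always counts pixels along the *short* equivalent side;
  images and specs are orientation-normalized on construction, because
  the short/long pairing with 26.0/34.6 mm is what matters, not
  landscape vs portrait.
* The short-side form of $S$ is canonical; the long-side form must agree
  within the 1% aspect tolerance and is used only as a consistency check.
* $u/f_{35} \le 0.1$ (object at or inside the focal plane) is a hard
  geometry error — there is no real image to measure.
* Geometry resolution precedence in the pipeline: explicit arguments or
  CLI flags, then metadata attached to the image, then a YAML config.
  EXIF autodiscovery is a stated limitation: no EXIF-capable R package is
  available to the package, so capture metadata must be supplied by the
  caller.

## Segmentation

### Plate circle

`detect_plate()` is a gradient-vote circular Hough search. Edge pixels
(gradient magnitude above `edge_floor = 5` times the median — a noise
floor, not a quantile, so a faint rim is not drowned out by one strong
food edge) vote for centers at $\pm r$ along their gradient direction for
radii in 8–47% of the short side, into a 4-px-binned accumulator that
tolerates direction noise. Raw votes decide the winner, so of two clean
circles the larger (longer rim) wins; the vote peak then seeds a
three-pass least-squares (Kåsa) refinement on annulus inliers. Two
robustness choices matter in practice: inliers must have near-radial
gradient directions (within ~35°), and weights are capped at their 70th
percentile — both stop a strong nearby food boundary from dragging the
fit off the faint rim. The score is angular rim coverage in [0, 1];
below `min_score = 0.5`, or on an effectively uniform image, the result
is a flagged not-found, never an exception. The plate is reported for
tableware area only — scale always comes from the capture geometry, so an
unusual plate cannot bias the area estimate.

### Food region

`segment_food()` smooths the region of interest (Gaussian, σ = 1 px),
takes the Otsu threshold, and extracts the boundary as the *sub-pixel
iso-intensity contour* at that level (`contourLines`). For a
high-contrast step edge the Otsu level sits mid-step where the gradient
peaks, so this contour is the edge locus, located to a fraction of a
pixel; it is also exactly the curve that separates pixel centers above
and below the threshold, which makes the polygon and the count
self-consistent. Among closed contours the largest-area one is taken
(noise specks lose); open contours, uniform crops, and crops whose two
intensity classes are closer than `min_contrast = 0.15` yield a flagged
not-found.

### Pixel counting

The package-wide inclusion rule is fixed: a pixel belongs to a region iff
its **center lies strictly inside the boundary polygon under the even-odd
rule**; centers exactly on the boundary are excluded. Pixel (row r,
col c), 0-based, has center (c + 0.5, r + 0.5); boxes are half-open. The
rule is deliberately oracle-checkable — the test suite verifies
`count_pixels()` exactly against an independently written per-point
ray-parity test on random polygons. The implementation is a scanline: per
row, edge crossings are sorted and centers strictly between crossing
pairs are counted, with vertex crossings handled by the half-open
`(y1 > py) != (y2 > py)` convention and horizontal edges never crossing.

## Area-to-weight calibration

Each food belongs to one of three morphology traits — block/thick bar,
slice/silk, grain/granule — looked up from a shipped 51-dish vocabulary
(trait is an *input*, never inferred from pixels). The shipped models
(204 observations each) are

```{r}
default_models()
```

`fit_area_weight()` refits the same form by unweighted OLS (`lm`) of
measured weight on machine-recognized area; unweighted because nothing in
the calibration design justifies a variance model, and the shipped
coefficients are reproduced exactly on noise-free data. Predictions below
zero — possible at very small areas since all intercepts are negative —
are clipped to 0 and flagged rather than returned negative: a weight
cannot be negative, and the flag preserves the information that the model
was extrapolating.

The area-correction model `machine = 0.7378 · actual + 12.765`
(R² 0.9591) is shipped with *machine area as the response*. The source
relation does not name its response variable; we adopt this orientation
because the machine-recognized area is systematically *smaller* than the
actual area, which this line reproduces for areas above ~49 cm² — the
relevant range for plated portions. `correct_area()` inverts it, floored
at 0. The correction defaults to **off** in the pipeline because the
weight models themselves regress on machine-recognized area; applying
both would correct twice. It is a single config switch for calibrations
built on actual areas.

## Validation statistics

`paired_t()`, `pearson()` and `one_sample_t()` wrap the standard
procedures (two-sided throughout; sidedness is a convention the package
fixes rather than exposes) and add explicit degenerate handling:
zero-variance differences return a flagged result — $t = 0, p = 1$ when
the mean already equals the null value, NA otherwise — instead of
infinities. `paired_t(x, y)` is exactly `one_sample_t(x - y, 0)`, and a
property test holds the two identical. `class_accuracy()` aggregates
per-class and overall percent correct with two-decimal formatting.
`validation_report()` bundles the three procedures for estimated-vs-
measured comparisons and serializes to JSON. No multiplicity correction
is applied — the battery is descriptive, not confirmatory.

## The synthetic scene generator

### What it emulates

The generator reproduces the capture protocol the shipped calibrations
assume: fixed $f_{35} = 46$ mm, shooting height 40.6 cm, top-down view,
uniform light background, one plate (default radius 8.5 cm), one food
region. The default camera is 640 × 480 (4:3), giving a pixel pitch of
~0.0424 cm/px and a 27.1 × 20.3 cm field of view — enough resolution
that discretization is far below the 3% closed-loop tolerance, while 50
scenes render in seconds. Food shapes are convex blobs (convex hull of a
radially jittered circle) scaled to an exact shoelace area; in
`random_scene()` the blob is placed so it stays inside the plate rim,
as plated food does.

Ground truth is computed before any noise: physical area by shoelace on
the cm polygon, pixel count by the package's own inclusion rule applied
to the cm→px mapped polygon (so the geometry chain is exactly
invertible), and weight from the trait model at the true area plus a
recorded Gaussian draw, floored at 0.

### Calibration records

`generate_calibration_set()` draws areas uniformly on **30–150 cm²** and
weights from the trait models plus Gaussian noise with per-trait sd

$$\sigma = |b|\,\mathrm{sd}(A)\sqrt{1/R^2 - 1},$$

which makes the simulated campaign reproduce each trait's published R²
(0.971 / 0.878 / 0.944) at $n = 204$ per trait. The lower bound 30 cm²
is chosen so every trait's mean weight is positive across the range
(the grain/granule line crosses zero at 28.2 cm²); below that, the
zero-floor on weights censors the low-area tail heavily enough to bias
OLS and break confidence-interval coverage, which would misrepresent the
estimator rather than the data. Weights that still fall below zero are
clamped to 0 (a physical floor, rare in this range).

### What it does not emulate

Real photographs bring texture, shadows, specular highlights on
tableware, mixed and overlapping foods, non-planar food (height above
the plate violates the single-object-plane assumption and biases area
low), perspective at off-vertical angles, lens distortion, and motion
blur — none of which are rendered. Passing the closed-loop suites
therefore demonstrates that the *geometry and counting chain is
self-consistent and correctly implemented*, not that segmentation is
robust on real food photography; the flat-intensity, high-contrast
scenes are easy by design so that failures indicate logic errors, not
scene difficulty.

## Problem sizes and budgets

The test suite renders 640 × 480 scenes: 10 seeded scenes for the
detection properties, 50 for closed-loop area recovery; the parameter-
recovery suite runs 100 replicates of 204 records × 3 traits; the
pixel-count oracle compares 100 random polygons on a 12 × 12 grid
(brute force is quadratic, so small grids keep the oracle honest and
fast). The whole suite runs in well under a minute; the acceptance
script, which repeats these end-to-end plus a 100-scene validation run,
takes about half a minute.

## Known limitations

* Trait must come from the label vocabulary or the caller; there is no
  visual trait inference.
* The 51-dish vocabulary and the three shipped models transfer only as
  far as the original calibration conditions do; refitting with
  `fit_area_weight()` on local data is the intended path.
* One food region per estimate: multi-dish plates need per-dish region
  boxes.
* No EXIF reading; capture geometry is caller-supplied.
* Lens distortion and perspective correction are out of scope; the
  method assumes a top-down view of a planar food extent.
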