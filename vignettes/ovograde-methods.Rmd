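---
title: "Density-based egg grading: models, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based egg grading: models, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovograde)
```

## The measurement model

`ovograde` rests on one physical fact: an egg loses water through its
shell pores during storage, so its mass — and, at essentially constant
volume, its density — falls monotonically with time. Density is therefore
a freshness proxy that needs no water bath.

Four closed-form quantities connect a weight reading and two image-derived
axes to a grade:

* **Shape index** `SI = (B/L) · 100 %`, with L the long-axis extent and B
  the maximum transverse extent, both in mm. SI is scale-free; a sphere
  scores 100 and hen eggs typically 72–78.
* **Volume** `V = π L B² / 6` mm³ — the egg as a spheroid of revolution
  about its long axis. This is the standard single-view estimator; it
  ignores the asymmetry between the blunt and pointed poles, an error the
  calibration chain absorbs in practice.
* **Density** `ρ = m / V` in g/mm³. Fresh-egg densities are of order
  10⁻³ g/mm³, so reports also render `ρ × 10⁶`.
* **Freshness** `F = ρ_E / ρ_HE · 100 %`, the current density relative to
  the fresh-laid ("highest-freshness") density `ρ_HE` of the egg's size
  class. F is linear in `ρ_E` by construction, which is why the
  freshness–density relation fits a straight line with R² = 1 whenever
  both come from the same measurements.

Internally density is always g/mm³; the ×10⁻⁶ convention appears only in
display fields (`density_1e6`). Rounding to the printed two decimals
happens at presentation and at classification boundaries (below), never
inside a computation, so chained quantities do not accumulate rounding
error.

## Grading scheme

Size classes are the commercial weight intervals, closed on both ends at
their printed two-decimal bounds: 0 jumbo 70–100 g, 1 extra-large
65–69.99 g, 2 large 60–64.99 g, 3 medium 55–59.99 g, 4 small 50–54.99 g.
Because the bounds are printed to 2 dp, weights are rounded to 2 dp before
the interval test; anything outside 50–100 g is *unclassified* and grades
without a freshness percentage (there is no reference density to divide
by), with a warning.

The freshness bands derive from two statistics of a storage experiment:
the mean of the per-size maximum (fresh-laid) densities, `ρ_max` (default
1072.60 × 10⁻⁶ g/mm³, the mean of the built-in per-size reference
densities), and the mean of the per-size minimum densities, `ρ_min`
(default 983.41 × 10⁻⁶, supplied as a constant because only the per-size
maxima ship as defaults). Their difference is split into three equal
bands of width `(ρ_max − ρ_min)/3` = 29.73 × 10⁻⁶, placing thresholds at

```{r}
default_grading_scheme()
```

The scheme is **global** — one threshold pair for all sizes — which is how
the banding is defined; per-size reference densities enter only through
the freshness percentage. Both the reference densities and `ρ_min` are
overridable via a YAML/JSON config (`read_grading_config()`), so the
scheme can be recalibrated to another flock without touching code.

Two boundary conventions are deliberate:

* the medium band is closed (`t_low ≤ ρ ≤ t_high`); high and low are
  strict inequalities;
* the comparison happens at the thresholds' printed precision (2 dp on
  the ×10⁻⁶ scale). The exact derived lower threshold is
  1013.1407 × 10⁻⁶; a density quoted as the published boundary
  1013.14 × 10⁻⁶ would otherwise fall *below* it, which contradicts the
  published closed medium range. Rounding both sides to the printed
  precision is monotone, so the partition and ordering properties are
  untouched.

The band-width difference is always computed from the two means, never
hard-coded, so a config override propagates consistently.

## The vision pipeline

The imaging path assumes the contrast regime of a purpose-built rig: a
single bright, convex egg on a darker, roughly uniform background, camera
vertically above. Under that assumption the pipeline is deliberately
plain:

1. **Denoise + grayscale** — colour channels collapse to luminance; a
   3×3 median filter (radius 1, configurable) removes shot noise without
   displacing the contour. The smallest window that kills single-pixel
   outliers was chosen because every extra pixel of window erodes the
   tips of the egg, which is exactly where the length measurement lives.
   A constant image is returned unfiltered — it is its own median, and
   skipping avoids the filter backend's 16-bit requantisation.
2. **Segment** — global Otsu threshold, keep the largest connected
   component, fill interior holes. Otsu-plus-largest-component was
   preferred over edge detection and linking because it is parameter-free,
   robust to the illumination gradient the rig leaves behind, and its
   failure mode ("no egg detected") is explicit. A foreground touching
   the image border raises a truncation warning rather than an error.
3. **Measure** — orientation from the second central moments of the
   foreground coordinates; the length is the Feret (maximal) extent of
   pixel centres along that axis and the breadth the maximal extent along
   the perpendicular, both as inclusive pixel counts (`max − min + 1`,
   0-based row/col coordinates). The global maximal perpendicular extent
   is used — not the width through the centroid — matching the definition
   of B as the *maximum* breadth. Axes swap if needed so length ≥ breadth
   always holds. Principal-axis extents, unlike the axis-aligned bounding
   box, make the measurement rotation-invariant to within about one
   pixel.
4. **Calibrate** — a single isotropic mm-per-pixel scalar, from a
   reference object of known diameter (`calibrate_scale()`). Perspective
   distortion along the optical path is an accepted error source, not
   modelled.

At the default working scale of 0.15 mm/px an egg spans roughly 330–430
px, so a one-pixel measurement error is ≈ 0.3 % — comfortably inside the
≤ 1 % mean recovery the tests demand.

## Synthetic data: what it emulates, what it does not

`render_egg()` draws a tapered ellipse: half-breadth profile
`b(u) = √(1−u²)(1 + taper·u)` along the normalised major axis u ∈ [−1, 1],
renormalised so the maximal perpendicular extent equals the requested
breadth. `taper` ∈ [0, 0.3] covers everything from a perfect ellipse to a
distinctly pointed egg. Background/foreground gray levels (defaults
40/200 with an enforced contrast floor of 50), an additive linear
illumination gradient and clipped additive Gaussian noise emulate the
LED-lit dark-box photographs the pipeline is designed for.

Ground truth must be *exact* for ±1 px assertions to mean anything, so at
orientations that are multiples of 180° the rasteriser discretises the
membership test on the pixel grid: parity offsets align the shape's
extremes with pixel centres, the profile is renormalised over the discrete
column grid, and a tip fill keeps the extreme columns non-empty. The
brute-force tight extents of the noiseless mask then equal
`length_px × breadth_px` exactly, by construction, for any taper. At other
orientations the continuous outline is sampled at pixel centres and
extents are exact to within about a pixel.

The renderer does **not** model shadows, specular highlights, perspective,
shell texture or multi-egg scenes. Passing the recovery tests therefore
shows the measurement chain is correct and robust to noise and pose — not
that it would survive a badly lit scene with reflections; on real rigs the
calibration photograph should be taken under the same optics as the eggs.

`generate_storage_series()` draws
`normalized_weight(x) = intercept + slope·x + ε`, `ε ~ N(0, σ²)` i.i.d.
per day including day 0, and `weight = initial_weight · normalized_weight`.
It is linear by design — the decay the models describe is linear over the
30-day window — and offers no exponential drying alternative. The
`intercept` field (default 1, i.e. exact day-0 normalisation) exists so
the generator can also emulate fitted decay lines, whose intercepts come
out near 1.003 rather than exactly 1. Both generators take a mandatory
seed and are byte-reproducible.

## Storage models and agreement statistics

`fit_linear()` is ordinary least squares via `stats::lm`, reporting slope,
intercept and `R² = 1 − SS_res/SS_tot`; the test suite cross-checks it
against an independently coded normal-equations oracle. A zero-variance
response is flagged `degenerate` with `R² = NA` — an undefined R² is
reported as undefined, never silently as 0 or 1. Raw weight series are
normalised by the day-0 weight (`fit_storage()`), with the intercept left
free; fitted intercepts near 1.003 rather than 1 are the expected
signature of noise at day 0.

`agreement_metrics()` implements the chemometric comparison of a
measurement chain against a reference method: per-item relative errors
`|measured − reference|/reference · 100` with their mean and max, the
complementary accuracies, OLS slope and R² of measured on reference,
`RMSEC = √(Σ(measured−reference)²/n)`, and the residual prediction
deviation `RPD = SD(reference)/RMSEC` — the standard convention, since
RPD definitions vary across the literature. A perfect chain has RMSEC 0
and RPD flagged infinite.

## Numerical choices and degenerate inputs

* Validation is strict: non-positive weights, axes, densities or masses
  are errors, as is breadth > length.
* The sphere (`B = L`, SI = 100) is a valid limit, used in tests.
* Threshold derivation refuses a degenerate scheme
  (`ρ_min ≥ mean maximum`).
* `fit_linear` refuses a constant predictor; `n ≥ 2` everywhere.
* Pixel coordinates are 0-based (row, col); extents are inclusive counts.
  This must be fixed for any ±1 px statement to be well defined.
* The measurement path contains no randomness, so re-running a batch
  writes byte-identical CSV.

## Problem sizes

The test suite and the acceptance script work at sizes chosen to exercise
the claims while staying quick on a laptop: 50 rendered eggs (≈ 400 px
long axis, noise σ = 10 gray levels, random pose) for end-to-end axis
recovery; 20 orientations of one egg for rotation invariance; 200
Monte-Carlo series of 31 days at σ = 0.002 for slope recovery; 100 random
small instances for the OLS oracle; 10,000 random densities and weights
for the partition and classification properties.

## Known limitations

* One egg per frame; no crack detection, candling or interior quality.
* A single species' grading scheme; duck or quail schemes would need
  their own intervals and reference densities via config.
* Volume inherits the spheroid assumption; strongly asymmetric eggs bias
  volume (and hence density) slightly low or high depending on taper.
* The freshness percentage is only as good as the per-size reference
  densities; a flock with different fresh-laid densities needs
  recalibration before the bands mean anything.
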