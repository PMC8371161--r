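# ovograde

Non-destructive grading and freshness assessment of chicken eggs from a
top-down photograph and a weight reading.

Egg freshness is classically checked by flotation or water displacement:
as an egg ages, water evaporates through the shell pores, its density
falls, and it floats. Those tests are slow and effectively destructive —
eggs absorb water. `ovograde` implements the dry alternative: measure the
egg's **length L** and **breadth B** (mm) with machine vision, take its
**weight m** (g) from a scale, and compute everything else:

- shape index — `SI = (B / L) × 100 %`
- volume (spheroid model) — `V = π L B² / 6` (mm³)
- density — `ρ = m / V` (g/mm³, displayed ×10⁻⁶)
- freshness — `F = ρ_E / ρ_HE × 100 %`, where `ρ_HE` is the fresh-laid
  (highest-freshness) density of the egg's size class
- size class — weight intervals 0 jumbo (70–100 g), 1 extra-large
  (65–69.99 g), 2 large (60–64.99 g), 3 medium (55–59.99 g),
  4 small (50–54.99 g)
- freshness band — the density span between the mean per-size maximum
  density (1072.60 × 10⁻⁶ g/mm³ by default) and the mean per-size minimum
  (983.41 × 10⁻⁶) is split into three equal bands of 29.73 × 10⁻⁶, giving
  thresholds at 1013.14 × 10⁻⁶ and 1042.87 × 10⁻⁶: below is low, above is
  high, the closed interval between is medium freshness.

The vision path is the standard high-contrast pipeline for a dark matte
enclosure: median denoise, grayscale, global Otsu threshold, largest
connected component, hole fill, then Feret extents along and perpendicular
to the second-moment principal axis, converted to millimetres by a single
mm-per-pixel calibration scalar. Storage behaviour is modelled by ordinary
least squares on the day-0-normalised weight, which decays linearly at
roughly −0.0023 to −0.0031 per day at room temperature.

Everything is testable without hardware: a seeded renderer produces egg
images with exact geometric ground truth, and a seeded series generator
produces linear weight-decay curves with Gaussian noise.

## Worked example

Grading from known measurements (the jumbo-class reference row):

```r
library(ovograde)
grade_egg(egg_measurement(weight = 70.60, length = 60.75, breadth = 45.60))
#>   weight length breadth shape_index   volume     density density_1e6
#> 1   70.6  60.75    45.6    75.06173 66141.58 0.001067407    1067.407
#>   size_class size_label freshness freshness_band
#> 1          0      jumbo       100           high
```

A shape index of 75.06 % and a density of 1067.41 × 10⁻⁶ g/mm³: this egg
sits exactly at its class's fresh-laid reference density, so its freshness
is 100 % and it lands in the high band (> 1042.87 × 10⁻⁶).

The same record from an image instead of calipers — here a rendered
synthetic egg with known 60.75 × 45.60 mm axes at 0.15 mm/px, noise and a
37° pose:

```r
egg <- render_egg(synthetic_egg_spec(405, 304, taper = 0.15, orientation = 37,
                                     noise_sigma = 10, seed = 7))
m <- measure_image(egg$raster, calibration_profile(0.15), weight = 66.79)
m
#> <egg_measurement> weight 66.79 g, L 60.69 mm, B 45.57 mm
grade_egg(m)
#>   weight   length  breadth shape_index   volume     density density_1e6
#> 1  66.79 60.69329 45.57178    75.08537 65998.08 0.001011999    1011.999
#>   size_class  size_label freshness freshness_band
#> 1          1 extra-large  92.84396            low
```

The axes are recovered to about 0.1 %; at 66.79 g this egg is extra-large,
and its density of 1012.00 × 10⁻⁶ — just under the 1013.14 × 10⁻⁶ cut —
grades it low freshness at 92.8 % of its class's fresh-laid density.

The same pipeline is scriptable from a shell via `inst/cli/ovograde.R`
(`measure`, `batch`, `synth-eggs`, `synth-storage`, `fit`, `thresholds`).

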