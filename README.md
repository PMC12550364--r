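# endoct

Quantitative analysis of helical-scan **endoscopic optical coherence
tomography (OCT)** of the mouse colon, built for longitudinal monitoring of
DSS-induced colitis. The package is aimed at biomedical imaging groups who
acquire catheter/endoscope OCT of tubular organs and want a tested,
reproducible path from the raw A-scan stream to study-level statistics:

* **reconstruction** — frame the helical A-scan stream into B-scans,
  log-compress, render circular (polar) cross-sections, extract enface
  views at fixed depth below the tissue surface;
* **segmentation** — Canny edge detection, hole filling, morphological
  closing, sheath removal, and per-A-line wall-band extraction with
  boundary refinement; flattening aligned on the detected surface;
* **quantification** — wall thickness profiles at 10 pullback locations
  and per-layer attenuation coefficients from Beer-Lambert fits;
* **statistics** — two-way group x day ANOVA (Type II) of thickness and
  attenuation, with the group x day interaction carrying the colitis
  signal;
* **synthetic phantom** — a four-layer cylindrical colon wall generator
  (speckle, sheath rings, detachment gaps, motion jitter, crypt texture,
  colitis effect schedules) with exact ground truth, so the whole chain is
  testable without instrument data.

## The model at the core

Detected intensity in a homogeneous layer follows the round-trip
Beer-Lambert law

```
I(z) = I0 * exp(-2 * muA * z),      muA = mu_s + mu_a   [1/mm]
```

with `z` the physical depth below the layer's top interface and the factor
2 accounting for the probe beam's double pass. The attenuation coefficient
is recovered as `-slope/2` of an ordinary least-squares fit of `ln I`
against `z`, after averaging A-scans in linear intensity to suppress
speckle. Wall thickness is `(bottom - top) * pitch / n` micrometres from
the segmented band, with `pitch` the axial sampling in air and `n` the
tissue group refractive index. Acute colitis expresses itself as the
interaction term of a `response ~ group * day` ANOVA: thickness rises and
attenuation falls at peak inflammation (day 9) in challenged mice only,
with recovery by day 24.

## Worked example

```r
library(endoct)

geom <- scan_geometry(a_lines_per_bscan = 240, n_bscans = 20,
                      n_depth_samples = 300)
geom
#> ScanGeometry:
#>   rotation 2400 rpm (40 frames/s), A-line rate 100 kHz
#>   pullback 12 mm at 0.1 mm/s (120 s)
#>   volume 20 B-scans x 240 A-lines x 300 depth samples
#>   axial pitch 5 um (air), n = 1.38; sheath 0.95-1.15 mm

# a synthetic colon with speckle, a detachment gap and crypt texture
sim  <- simulate_volume(phantom_spec(seed = 7), geom)
wall <- segment_volume(sim$volume)
dice_coefficient(mask_array(wall), sim$truth$wall_mask)
#> [1] 0.9908757

profile <- sample_thickness(thickness_map(wall, geom), geom,
                            n_locations = 10)
head(profile, 3)
#>   location position_mm thickness_um
#> 1        1         0.6     391.3043
#> 2        2         1.8     380.4348
#> 3        3         3.0     376.8116

# a full longitudinal study: 2 groups x 3 mice x days 0/9/24
study <- simulate_study(study_design(seed = 1), phantom_spec(),
                        colitis_effect(), geom, render = "truth")
quant <- quantify_study(study, geom, measures = "thickness")
two_way_anova(quant, "thickness_um", layer = "wall")
#>        term df statistic      p_value signif
#> 1     group  1  72.00432 2.046523e-06    ***
#> 2       day  2  47.74657 1.935543e-06    ***
#> 3 group:day  2  43.88399 3.027890e-06    ***
#> 4 Residuals 12        NA           NA
```

The Dice coefficient is the overlap between the detected wall band and the
generator's ground-truth mask (1 = perfect). The thickness profile is the
per-bin median along the 12 mm pullback; the phantom's baseline wall is
380 µm. In the study table, the strongly significant `group:day`
interaction is the colitis signature: only challenged mice change at
day 9 (wall x1.5 thicker, attenuation x0.7) and largely recover by day 24.

`run_pipeline(out_dir, design, phantom, effect, geom)` performs the whole
chain (simulate -> segment -> quantify -> ANOVA) and writes `quant.csv`,
`anova_thickness.csv`, `summary.csv` and a `manifest.json`; the same seed
reproduces all outputs bit-for-bit.

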