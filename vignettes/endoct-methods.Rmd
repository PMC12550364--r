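---
title: "Methods: quantifying murine colitis from endoscopic OCT"
author: "endoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying murine colitis from endoscopic OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoct)
```

## The measurement problem

Acute DSS colitis in mice thickens the colon wall (oedema and immune-cell
infiltration) and lowers its optical attenuation coefficient (disruption of
the mucus layer and altered solute concentrations change the refractive
index contrast that drives scattering). A side-viewing endoscopic
swept-source OCT probe rotating at 2400 rpm while being pulled back at
0.1 mm/s samples the colon wall on a helix: one B-scan (a full
cross-section of A-scans) per revolution, 12 mm of colon in 120 s. `endoct`
turns that A-scan stream into two longitudinal biomarkers — wall thickness
and the per-layer Beer-Lambert attenuation coefficient — and tests their
group-by-day structure with a two-way ANOVA.

Because no raw instrument data are publicly deposited, the package ships a
first-class synthetic phantom generator with exact ground truth; every
accuracy claim in the test suite is a comparison against that ground truth.

## Signal model

Within a homogeneous layer, detected OCT intensity decays with physical
depth $z$ according to the round-trip Beer-Lambert law

$$ I(z) = I_0 \, e^{-2(\mu_s + \mu_a) z} = I_0 \, e^{-2 \mu_A z}, $$

where $\mu_A = \mu_s + \mu_a$ (mm⁻¹) is the total attenuation coefficient;
the factor 2 accounts for the double pass of the probe beam. At 1310 nm,
absorption in soft tissue is small, so $\mu_A$ tracks scattering and hence
refractive-index contrast. Only the sum $\mu_s + \mu_a$ is identifiable
from an intensity fit, which is why the phantom parameterises layers by
$\mu_A$ directly.

`fit_attenuation()` estimates $\mu_A$ as $-\text{slope}/2$ of an ordinary
least-squares fit of $\ln I$ on $z$. On noiseless exponentials this is the
exact maximum of the nonlinear least-squares objective too, and the test
suite asserts machine-precision recovery; on speckled data the package
averages A-scans in *linear* intensity first (the speckle is unit-mean
there, so the average is unbiased, whereas averaging log-intensity
under fully developed speckle carries the Euler–Mascheroni bias). A
nonlinear fit buys nothing once averaging has been done and is not the
default.

Depth calibration: depth samples are `axial_pixel_pitch` micrometres apart
in air; physical tissue depth divides by the group refractive index
(default 1.38, a typical soft-tissue value — the acquisition never states
its own calibration, so this is configurable).

## The synthetic phantom

`phantom_spec()` describes a four-layer cylindrical wall — colonic mucosa,
muscularis mucosa, submucosa, muscularis propria (lumen to serosa) —
wrapped around a transparent probe sheath rendered as two thin bright
rings. Defaults are murine-plausible: thicknesses 200/30/50/100 µm,
attenuations 2.5/1.6/1.1/2.0 mm⁻¹, and they are deliberately arbitrary:
all accuracy checks compare against the generated truth, not against these
numbers.

The generator emulates the features the analysis has to survive:

* **speckle** — multiplicative unit-mean exponential intensity noise
  (fully developed speckle); a Rayleigh-amplitude alternative can be
  swapped in via `speckle_model`;
* **noise floor** — additive background with its own speckle;
* **specular interface spikes** — a single-sample reflectivity spike at
  each layer top (`interface_gain`);
* **sheath-detachment gaps** — angular spans where the wall lifts off the
  sheath by up to `max_radial_offset` µm (raised-cosine bump);
* **per-frame motion jitter** — rigid radial and angular displacement per
  B-scan;
* **crypt texture** — an angular modulation of mucosal reflectivity whose
  pattern is stored in the ground truth so enface views can be validated;
* **colitis effects** — `colitis_effect()` multiplies layer thicknesses
  and attenuations per day (defaults: ×1.5 thickness and ×0.7 attenuation
  at day 9, near-recovery at day 24, baseline exactly 1 at day 0).

What the phantom does **not** model: wave optics, coherent interference at
interfaces, NURD (non-uniform rotational distortion), vasculature, and any
mechanistic link between inflammation and refractive index — the effect
multipliers are purely phenomenological. Passing tests therefore show the
*pipeline* is correct under the stated noise model, not that the biology
is simulated faithfully.

Random streams are keyed per (mouse, day) from the study seed, so studies
are bit-reproducible and adding a mouse never perturbs existing draws.
Between-session variability is modelled as independent lognormal
multipliers (sdlog 0.05) on thickness and attenuation per mouse-day,
representing combined animal and probe-repositioning variability. A
*persistent* per-mouse component is deliberately not part of the default:
it would correlate a mouse's measurements across days, which the plain
two-way fixed-effects ANOVA used here (and in the field) does not model —
a known limitation worth remembering with real data, where a mixed model
would be the upgrade path.

## Segmentation

Each B-scan is processed as: log-compression → Canny edge detection →
hole filling → morphological closing → sheath removal → wall-band
extraction → boundary refinement.

Design choices that were genuinely open, and how they were settled:

* **Edge detection operates in dB.** In linear intensity, speckle gradient
  magnitude scales with local brightness; in dB it is additive and
  comparable across depth.
* **The dB floor is estimated per frame** (`estimate_noise_floor()`: 4× the
  median of the deepest tenth of the image). Without this, background
  speckle — whose dB variance equals tissue's — floods the edge map with
  spurious edges.
* **The sheath rings are suppressed before edge detection** (their depth
  position is known hardware geometry). Left in, their specular gradients
  dominate the relative Canny thresholds and starve tissue edges;
  `build_wall_mask()` removes the same depth band again before component
  selection, so either path alone is safe.
* **Wall selection takes the union of all non-speck components**, not only
  the largest. The Canny map of a layered, speckled B-scan is a family of
  thin interface curves plus interior edgelets; morphological closing
  cannot weld thin curves (the erosion half removes any thin bridge), so a
  largest-only rule collapses the wall to a single interface. Since the
  frame-adaptive floor leaves the background edge-free, every surviving
  component lies inside the wall and the per-A-line first/last foreground
  of their union is exactly the band. `min_component_px` (default 3) and
  `rel_component` filter stray specks for noisier data.
* **Boundary refinement** (`refine_boundaries()`): the gradient maximum of
  a smoothed one-sided flank sits about σ/2 *outside* the physical
  interface, so the raw Canny band is systematically one sample too wide
  per side — which alone would consume the whole thickness error budget.
  The top is snapped to the specular interface spike (local maximum of the
  across-A-line-smoothed linear image), the bottom to the half-level
  crossing of the exit step.
* **Gap policy**: A-lines with no wall are bridged by circular linear
  interpolation across gaps up to 15° and left missing beyond that
  (excluded from quantification). Canny parameters default to σ = 2 px and
  relative hysteresis (0.1, 0.3); closing uses a disk of radius 6 px. The
  closing order (dilate, then erode) follows the usual reading of
  "dilation and erosion" as a closing.
* **Coordinates** are 0-based with half-open bands `[top, bottom)`
  throughout; depth index 0 faces the probe.

Flattening shifts each A-line up by its top boundary (surface at row 0),
stores the shifts, and is exactly invertible on in-wall pixels — this also
absorbs per-frame radial motion jitter, which is why no frame registration
is attempted. Per-layer boundaries within the wall are *not* segmented
from images: at 5 µm axial sampling the thinner murine layers are only a
few samples thick, so layer windows come from configuration or from
generator ground truth.

## Quantification

* **Thickness**: `(bottom − top) × pitch / n` per A-line; the profile is
  the per-bin median over 10 equal pullback bins (median, because boundary
  outliers at detachment edges are heavy-tailed). Evenly spaced bins are a
  convention choice — operator-chosen locations would be equally valid and
  are not modelled.
* **Per-layer attenuation**: per pullback bin, A-scans are averaged in
  linear intensity and fitted per layer with a 3-sample specular-peak
  guard at both window ends. When per-A-line layer boundaries are
  available (ground truth, or any external source), each A-scan is
  re-aligned on its own layer top before averaging: with fixed
  surface-relative windows, boundary undulation smears the averaged
  interfaces and visibly biases thin-layer fits. Bins with under 25% valid
  A-lines, or windows shorter than 4 samples, are reported missing rather
  than imputed — with the default (realistic) layer thicknesses the
  30 µm muscularis mucosa is genuinely unmeasurable at this sampling,
  and the package says so instead of guessing.
* **Baseline normalisation**: percent change from each mouse's own day-0
  mean, matching the convention of reporting longitudinal change against
  the pre-induction state.

## Statistics

`two_way_anova()` fits `response ~ group * day` with Type II sums of
squares (`car::Anova`), which handles unbalanced tables and reduces to the
classical decomposition when balanced. The colitis signal is the
group × day interaction: an effect present only in challenged mice at
peak inflammation. By default the analysis unit is the mouse-day mean —
the 10 pullback locations of one mouse are not independent replicates and
using them as such inflates power; a `unit = "location"` mode exists,
clearly labelled, for comparison. No post-hoc tests are run; significance
is annotated with the usual star convention (*** at p ≤ 0.001).

Calibration, checked by simulation in the test suite: under a null effect
schedule the interaction rejects at ≈4–5% at α = 0.05 over hundreds of
simulated studies (the slight conservatism comes from the right-skew of
the lognormal session noise), and under the default effect (×1.5 / ×0.7,
n = 3 per group) the interaction is essentially always significant at
p < 0.01 — the day-9 effect directions being thickness up, attenuation
down.

## Numerical conventions and problem sizes

Polar rendering maps A-line *i* to angle 2πi/N counter-clockwise from the
+x axis and uses bilinear interpolation (nearest-neighbour available for
exactness tests). Intensity volumes round-trip through 32-bit float
multi-page TIFF with the normalisation factor stored in a YAML sidecar.
dB conversion is `20·log10(I/floor)`, clipped at the floor.

Tests and the acceptance script run the phantom at 90–360 A-lines,
4–50 B-scans and 300–400 depth samples rather than the instrument's
5012 × 4050 × 560 — the algorithms are resolution-independent and these
sizes keep a full study in memory while exercising every artifact
(detachment, jitter, speckle, crypts). ANOVA calibration and power use the
generator's ground-truth rendering path (boundaries and true attenuations
without image formation), since they exercise study-level statistics, not
image processing.

## Known limitations

* Absolute attenuation values from in-vivo colons are not reproducible
  here (no deposited data; published box plots print no axis values), so
  all attenuation checks are recovery and ratio checks against generated
  truth.
* The 4050 B-scan and 5012 A-scans/B-scan counts quoted for the instrument
  are mutually inconsistent with its 2400 rpm × 120 s geometry (which
  gives 4800 revolutions) and its 100 kHz sweep rate (2500 A-scans per
  40 fps frame); the geometry type therefore accepts recorded counts
  verbatim and never derives them.
* Automatic intra-wall layer segmentation, NURD correction,
  depth-resolved (per-pixel) attenuation mapping and mixed-effects
  longitudinal models are out of scope.
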