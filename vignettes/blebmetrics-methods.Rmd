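---
title: "Methods: quantifying large-volume subcutaneous injections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying large-volume subcutaneous injections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebmetrics)
```

## The measurement problem

Re-formulating biologics for subcutaneous (SC) delivery often requires
injections above 2 mL. Characterizing how such an injection behaves in
tissue requires three simultaneous readouts:

1. **Dispersion** — how widely the injected fluid pocket (the *bleb*)
   spreads in the SC space, visible on CT when the injectate carries
   iodinated contrast;
2. **Skin distension** — how much the injection raises the skin above its
   pre-injection surface;
3. **SC pressure** — the pressure transient recorded by an inline sensor
   during and after the infusion.

`blebmetrics` implements the full analysis chain for these readouts, plus a
synthetic generator that produces CT-like phantom series and pressure
recordings with known ground truth, so the chain is testable end to end
without any animal data.

## Bleb morphometry

### Segmentation

The contrast-filled bleb is orders of magnitude brighter than soft tissue
(iodinated contrast is in the thousands of HU against tissue at tens of
HU), so `segment_bleb()` uses seeded threshold region growing: voxels at or
above a threshold form the candidate set, one binary closing pass with a
radius-1 ball fills small holes (the computational stand-in for manual
touch-up), and the connected component containing a user-supplied seed
voxel (26-connectivity by default, configurable) becomes the mask. The
`"auto"` threshold is the midpoint between the modal whole-volume intensity
(background tissue dominates the histogram) and the modal intensity of a
5×5×5 neighbourhood around the seed; for high-contrast injectate the two
modes are separated by thousands of HU and the midpoint is extremely
robust.

### Semi-axes and surface area

The bleb is modelled as an ellipsoid. `measure_semi_axes()` takes half the
axis-aligned extent of the mask along each grid axis — the computational
equivalent of caliper measurements on orthogonal image views — rather than
principal-component axes; this matches how the dimensions are defined for
the surface-area model and keeps results interpretable slice by slice.
Dispersion is summarized by the closed-form ellipsoid surface-area
approximation

$$S \approx 4\pi \left[ \frac{a^p b^p + a^p c^p + b^p c^p}{3} \right]^{1/p},
\qquad p = 1.6,$$

which is exact for spheres and accurate to about 1% over the aspect ratios
blebs take in practice. We keep the exponent at 1.6 (configurable) rather
than the 1.6075 sometimes quoted; the difference is far below the
rasterization error of any realistic scan. `ellipsoid_surface_area_quadrature()`
provides an independent numerical surface integral for validation; the
closed form stays within 2% of it for aspect ratios up to 10 (this is
asserted in the test suite). A deliberate non-goal is mesh-based (marching
cubes) surface measurement: for regularly shaped blebs the three-axis
ellipsoid model is less sensitive to inter-slice interpolation and edge
smoothing, and it is what the axis measurements directly support.

## Skin distension

Distension is measured by overlaying pre- and post-injection volumes.
`extract_skin_surface()` reduces each volume to a lateral height map: per
lateral position, the height of the first voxel at or above an air
threshold (default −500 HU, halfway between air and any tissue) scanning
from the exterior. `measure_distension()` differences the post- and
pre-injection height maps, keeps the largest laterally connected region
with a difference of at least `min_height_mm` (default 0.5 mm, below one
voxel at typical spacing, suppressing quantization jitter), and summarizes
the region as a half-ellipsoid: lateral semi-axes from the region's
axis-aligned extents, height from the peak difference, and volume

$$V \approx \tfrac{2}{3}\pi a b c.$$

No image registration is performed; the workflow assumes
reduced-respiration acquisition keeps pre/post anatomy aligned, and
`check_alignment()` gates that assumption by scoring the mean absolute
intensity difference outside the bleb-plus-cap region against the noise
level (pure noise scores $2/\sqrt{\pi} \approx 1.13$; the default tolerance
is 2). Distension volumes are averaged over a configurable post-injection
window; the default is 90–120 s. A 90–180 s variant appears in some
reporting conventions, so the window is an explicit argument rather than a
constant.

## Pressure analysis

Pressure recordings arrive as uniformly sampled time/pressure tables
(10 Hz reference rate) in kPa; psi and mmHg converters are provided since
gauge software varies. With a pump at flow rate $q$ and volume $v$,
cessation is at $t_\mathrm{start} + 60 v / q$ — 27 s for 4.5 mL and 54 s
for 9 mL at 10 mL/min. `max_pressure()` searches the closed window
±2 s around cessation (ties: earliest sample). The post-injection decay
over the 2 min following the injection is modelled as a double
exponential,

$$P(t) = A_1 e^{-k_1 t} + A_2 e^{-k_2 t},$$

summarized by the effective decay constant

$$k_\mathrm{eff} = \frac{A_1 k_1 + A_2 k_2}{A_1 + A_2},$$

the amplitude-weighted mean of the two rates, which always lies between
them.

Numerical choices in `fit_decay()`:

* **Baseline.** A pure double exponential decays to zero, but real gauges
  have a resting offset, so a constant baseline is estimated jointly by
  default (it can be pinned). This makes the model well-posed on realistic
  traces; the amplitudes then describe pressure above baseline.
* **Clock origin.** The decay clock starts at the detected peak, clamped
  to be no earlier than cessation. The clamp matters: with noise, the
  maximum sample in the ±2 s window frequently lands on the rising ramp
  just *before* cessation, and anchoring there would pull still-rising
  samples into the decay fit and bias the amplitudes by several percent.
  With noiseless data peak and cessation coincide and the clamp is inert.
* **Initialization and restarts.** Curve peeling: a log-linear fit of the
  last third of the window seeds the slow component, a log-linear fit of
  the early residual seeds the fast one; five multiplicatively jittered
  restarts (fixed internal seed, so fits are deterministic) guard against
  local minima. Optimization is constrained Levenberg–Marquardt
  (`minpack.lm::nlsLM`) with $A_1, A_2 \ge 0$, $k_1, k_2 > 0$; components
  are reported with $k_1 \ge k_2$.
* **Degenerate input.** A flat trace either fails all restarts or returns
  negligible amplitudes with `identifiable = FALSE`.

## The synthetic generator

The generator defines the conditions under which the chain is validated.

* **Phantom geometry.** Anatomy is reduced to flat slabs along the depth
  axis — exterior air (−1000 HU), a 3 mm skin layer (150 HU), a
  subcutaneous layer (50 HU), a deep muscle-like slab (60 HU) — because
  flat slabs are the simplest geometry that exercises surface extraction.
  The bleb is a rasterized ellipsoid at 3000 HU (undiluted iodinated
  contrast); separability requires
  `contrast_hu > background_hu + 5·noise_sd`. The distension cap raises
  the skin-surface height field by a half-ellipsoid profile, so
  post-injection anatomy above the original surface exists exactly where
  the truth record says. Noise is i.i.d. Gaussian in HU; correlated CT
  noise textures, beam hardening and partial-volume effects are out of
  scope, as are curved anatomy and respiratory motion. Anisotropic voxel
  spacing (e.g. 3 mm slices) is supported throughout.
* **Dispersion kinetics.** No quantitative in-vivo dispersion kinetics are
  available to calibrate against, so the growth model is a deliberate
  stand-in: lateral semi-axes grow by a saturating factor
  $1 + g\,(1 - e^{-t/\tau})$ (defaults $g = 0.2$, $\tau = 120$ s) while
  the depth axis stays fixed, making the rasterized volume non-decreasing.
  Hyaluronidase (HLN), which degrades hyaluronan and lets the injectate
  spread, is emulated by a factor ≥ 1 multiplying the lateral growth and
  dividing the cap height — more dispersion, less distension.
* **Pressure traces.** Baseline, then a rise during infusion reaching
  `baseline + A1 + A2` at cessation, then the two-component decay, plus
  Gaussian noise. The rise is a linear ramp by default (constant-rate
  pump); a normalized first-order rise is available because inline sensors
  teed off the injection line show a slower early rise than syringe-mounted
  force sensors. Pressure units are never standardized across rigs; kPa is
  canonical here and absolute simulated amplitudes (peak ≈ 20 kPa at
  4.5 mL, ≈ 30 kPa at 9 mL, baseline 2 kPa, noise 2% of peak) are realistic
  choices for a viscous ~20 cP injectate, not reproductions of any
  measured value.

## The in-silico study design

`run_experiment()` replicates a 2-volume (4.5, 9 mL) × ±HLN factorial with
n = 3 replicates per arm, scanned at baseline, 5, 30, 60, 90, 120, 180 and
600 s. Per replicate it reports: bleb surface area at the 600 s (10 min)
scan, distension volume averaged over the window, maximum pressure near
cessation, and $k_\mathrm{eff}$. Replicates carry ~5% lognormal
between-subject variability on geometry and pressure amplitudes so that
group statistics are meaningful. HLN arms use a dispersion factor of 1.5,
a pressure-amplitude factor of 0.6 and decay rates ×1.3 — effect sizes
chosen once to represent a clearly active enzyme against ~5% biological
noise. Group comparisons use the classical pooled-variance two-sample
Student's t-test, two-sided at α = 0.05, no multiple-testing correction
(one test per endpoint); a Welch variant is available. Degenerate cases
follow fixed conventions: identical groups give t = 0, p = 1; zero
variance with unequal means is an explicit failure; n = 1 arms skip
statistics with a notice.

Default problem sizes — 80×80×44 voxels at 1.5 mm for pipeline phantoms,
64×56×48 at 1 mm for recovery checks, 100 noisy traces for fit-recovery
statistics, 500 simulated experiments (n = 20 per arm, maximum-pressure
endpoint) for type-I calibration of the t-test — were chosen so the entire
validation runs on a laptop in well under an hour while keeping Monte
Carlo error small relative to the tolerances checked.

## What passing tests do and do not show

The phantom suite demonstrates that the chain recovers known geometry and
decay parameters under its own assumptions: slab anatomy, ellipsoidal
blebs, aligned pre/post scans, Gaussian noise, and an exactly
double-exponential decay. Real scans add curved and heterogeneous anatomy,
irregular blebs (which become more common with repeated injections and
developing mammary/fibrous tissue), imperfect breath-hold alignment, and
sensor compliance effects — none of which the generator emulates. Passing
here validates the computations, not the biology; absolute in-vivo values
(surface areas, distension volumes, pressures) depend on animal, site and
formulation and are not reproduced by simulation.
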