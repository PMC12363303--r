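# blebmetrics

Quantitative characterization of **large-volume subcutaneous (SC)
injections** from CT image series and inline pressure recordings.
Biologics re-formulated for SC delivery often need injections above 2 mL;
developing such products requires measuring, in the same session, how the
injected fluid pocket (the *bleb*) disperses in the SC space, how much it
distends the skin, and what pressure it generates. `blebmetrics`
implements that analysis chain and a ground-truth synthetic generator so
every stage is testable without imaging data.

## What it computes

* **Bleb morphometry** — seeded threshold region growing segments the
  contrast-filled bleb; its axis-aligned semi-axes *a ≥ b ≥ c* (mm) feed
  the ellipsoid surface-area approximation

  S ≈ 4π [ (aᵖbᵖ + aᵖcᵖ + bᵖcᵖ) / 3 ]^(1/p),  p = 1.6,

  the dispersion readout, tracked over the scan schedule
  (`surface_area_timeseries()`).
* **Skin distension** — pre/post skin-surface height maps are
  differenced; the largest protruding region is summarized as a
  half-ellipsoid, V ≈ (2/3)π·a·b·c, with an alignment gate
  (`check_alignment()`) in place of registration.
* **Pressure analysis** — peak pressure within ±2 s of injection
  cessation (cessation = volume/flow·60 s; 27 s for 4.5 mL, 54 s for 9 mL
  at 10 mL/min), then a constrained double-exponential fit of the 2 min
  decay, P(t) = A₁e^(−k₁t) + A₂e^(−k₂t), summarized by the effective
  decay constant k_eff = (A₁k₁ + A₂k₂)/(A₁ + A₂).
* **Synthetic data** — layered tissue phantoms with a rasterized
  high-contrast bleb and half-ellipsoid skin cap (NIfTI-compatible,
  anisotropic spacing), and simulated pressure traces (ramp, peak,
  bi-exponential decay), both with exact ground truth and seeded
  determinism.
* **Study pipeline** — `run_experiment()` replicates a 2-volume × ±HLN
  (hyaluronidase) factorial, n = 3, with pooled two-sample t-tests per
  endpoint.

## Worked example

```r
library(blebmetrics)

# a 1 mm phantom: bleb semi-axes (20, 15, 8) mm, skin cap (10, 8, 4) mm
spec <- phantom_spec(grid_shape = c(64, 56, 48), spacing = c(1, 1, 1),
                     bleb_center = c(32, 28, 16), bleb_axes = c(20, 15, 8),
                     cap_axes = c(10, 8, 4), noise_sd = 20, seed = 7)
pp <- generate_phantom_pair(spec)

mask <- segment_bleb(pp$post, c(32, 28, 16), threshold = "auto")
#> <bleb_mask> 10080 voxels (10.1 mL) at threshold 1525.0 HU
measure_semi_axes(mask)
#>  a  b  c
#> 20 15  8
ellipsoid_surface_area(20, 15, 8)
#> [1] 2541.7

measure_distension(extract_skin_surface(pp$pre),
                   extract_skin_surface(pp$post), min_height_mm = 0.5)
#> <distension> a = 10.00, b = 8.00 mm, height = 4.00 mm, V = 0.6702 mL

prot <- injection_protocol(volume_ml = 4.5, flow_rate_ml_min = 10)
tr <- generate_pressure_trace(pressure_sim_spec(prot, seed = 7))
max_pressure(tr)$max_kpa
#> [1] 22.12
fit_decay(tr)
#> <decay_fit> A1 = 14, A2 = 6.06 kPa; k1 = 0.5069, k2 = 0.05036 1/s
#>   keff = 0.3688 1/s, baseline = 1.99 kPa, rss = 190 (n = 1201)
```

The segmentation recovers the phantom's 10 mL bleb and its exact
semi-axes; the fitted decay constants match the simulation's generating
values (A₁ = 14, A₂ = 6, k₁ = 0.5, k₂ = 0.05) to within the noise.

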