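# vfadose

Whole-volume gel dosimetry analysis via variable-flip-angle (VFA) R1
mapping.

MRI-readable Fricke gel dosimeters convert absorbed dose into Fe³⁺, which
raises the gel's longitudinal relaxation rate R1 = 1/T1 linearly with
dose. Imaging a whole irradiated vial with a fast 3D R1 mapping sequence
turns the gel into a true volumetric dosimeter — particularly valuable for
carbon-ion beams, whose sharp Bragg peak and steep lateral gradients defeat
point and planar detectors. `vfadose` is the analysis side of that
measurement, for medical physicists and gel-dosimetry researchers:

* **R1 mapping** — voxel-wise T1/R1 estimation from spoiled-gradient-echo
  (SPGR) magnitude volumes acquired at two or more flip angles, via the
  standard linearization
  `S/sin α = E1 · S/tan α + M0(1 − E1)`, `E1 = exp(−TR/T1)`,
  `T1 = −TR/ln E1`.
* **Calibration** — circular-ROI statistics, linear R1-vs-[Fe³⁺] (or
  R1-vs-dose) fits, and the radiation chemical yield
  `G(Fe³⁺) [µmol/J] = sensitivity [s⁻¹kGy⁻¹] / relaxivity [s⁻¹mM⁻¹] / ρ [kg/L]`.
* **Depth-dose analysis** — δR1 (irradiated − control) maps, beam-axis
  profiles with n×n neighbourhood averaging, Bragg-peak localization,
  percentage-depth-dose (PDD) normalization, and comparison against an
  ionization-chamber reference curve.
* **Synthetic phantom** — a parametric carbon pencil-beam in a virtual
  φ35 × 78 mm gel vial, dose→R1 mapping with depth-dependent sensitivity,
  and a simulated SPGR acquisition with k-space truncation (Gibbs ringing)
  and Rician noise, so the whole chain runs and validates with no scanner
  data. All stochastic outputs are seeded and bit-reproducible.

Volumes travel as NIfTI-1, protocols and pipeline configs as YAML,
profiles and calibration tables as CSV, reports as JSON. A thin CLI
(`inst/exec/vfadose`) wraps the pipeline (`simulate`, `fit-r1`,
`calibrate`, `gvalue`, `analyze`).

## Worked example

Simulate a 600 Gy carbon-beam study, map R1, and analyse the depth dose:

```r
library(vfadose)

spec <- phantom_spec(beam = beam_model(entrance_dose_gy = 600))
sim  <- simulate_acquisition(spec, seed = 1)

map_irr <- fit_r1_volume(sim$irradiated, sim$protocol)
map_ctl <- fit_r1_volume(sim$control, sim$protocol)
map_irr
#> R1 volume: grid 64x64x96, spacing 1x1x1 mm, 80802/393216 valid voxels
#>   R1 range 0.002451 .. 7.146 1/s (median 0.6571)

prof <- extract_depth_profile(delta_r1(map_irr, map_ctl), "z", n_slices_avg = 7)
str(find_bragg_peak(prof))
#> List of 2
#>  $ peak_depth_mm: num 49
#>  $ peak_value   : num 5.53

iq <- image_quality(map_ctl, c(32, 32, 45), 10, "xy", n_slices = 7)
str(iq[c("snr", "cv_percent")])
#> List of 2
#>  $ snr       : num 25.8
#>  $ cv_percent: num 3.87
```

The median fitted R1 (0.657 s⁻¹) sits at the unirradiated background of
0.65 s⁻¹; the peak δR1 of 5.53 s⁻¹ at 49 mm reflects the Bragg peak the
generator placed at 48 mm depth (profile depth origins carry ±1 voxel, see
the vignette), and the control-ROI CV (3.87% for this seed) lands on the 3.7% noise target.

Calibration and G-value:

```r
vials <- generate_calibration_vials()        # 0-0.5 mM Fe3+, CV 3.7%
fit_calibration_series(vials, seed = 1)
#> linear calibration: R1 = 0.6496 + 5.7017 * level  (R^2 = 1.00000)
#>   slope SE 0.0036 (propagated), 5 points

g_value(1.08, 5.7, 1.007)
#> G(Fe3+) = 0.188 +/- 0.001 umol/J
```

The fitted relaxivity (5.70 ± 0.004 s⁻¹mM⁻¹) recovers the generator's
ground truth of 5.7, and the yield computation reproduces the published
0.188 µmol/J from its three printed inputs.

## Layout

* `R/` — relaxometry, calibration, dose analysis, synthetic phantom,
  I/O and pipeline driver
* `tests/testthat/` — unit, property and end-to-end acceptance tests
* `vignettes/gel-dosimetry-vfa.Rmd` — the methods vignette: models,
  parameter choices, numerical decisions, limitations
* `scripts/acceptance.R` — headline-quantity reproduction (above)
* `inst/exec/vfadose` — command-line front end
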