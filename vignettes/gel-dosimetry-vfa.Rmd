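---
title: "Whole-volume gel dosimetry with variable-flip-angle R1 mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-volume gel dosimetry with variable-flip-angle R1 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Fricke-type gel dosimeters convert absorbed radiation dose into Fe³⁺, which
raises the longitudinal relaxation rate R1 = 1/T1 of the gel linearly with
dose. Reading a whole irradiated vial with a quantitative 3D R1 map turns
the gel into a volumetric dosimeter — attractive for ion beams, whose Bragg
peak and steep lateral gradients are poorly served by point or planar
detectors. The bottleneck is acquisition time: classical inversion-recovery
T1 mapping of a 3D volume is far too slow, while the variable-flip-angle
spoiled-gradient-echo (VFA-SPGR) method maps T1 from as few as two fast 3D
acquisitions.

`vfadose` implements the complete analysis chain for this measurement —
R1 mapping, Fe³⁺ calibration, dose-difference (δR1) depth-dose analysis and
radiation-chemical-yield computation — together with a synthetic phantom
generator that emulates the carbon-beam irradiation and the MR acquisition
(including its two dominant artifacts, Rician magnitude noise and k-space
truncation ringing), so every stage can be validated end to end without
scanner data.

## Signal model and R1 estimation

The spoiled gradient echo signal at flip angle $\alpha_i$ is

$$S_i = M_0\,\frac{(1 - E_1)\,\sin\alpha_i}{1 - E_1\cos\alpha_i},
\qquad E_1 = e^{-TR/T_1},$$

which linearizes to

$$\frac{S_i}{\sin\alpha_i} = E_1\,\frac{S_i}{\tan\alpha_i} + M_0(1 - E_1).$$

`vfa_fit_voxel()` fits this line by ordinary least squares over the
acquired angles — with the standard two-angle protocol (7° and 36° at
TR = 15 ms) that is the exact two-point line — and recovers
$T_1 = -TR/\ln E_1$ and $M_0$ from slope and intercept. `fit_r1_volume()`
applies the fit voxel-wise and reports R1 = 1000/T1 in s⁻¹.

Numerical contracts, verified by the test suite:

* the noiseless round trip signal → fit recovers (T1, M0) to a relative
  error below 1e−8 for T1 anywhere in 200–4000 ms;
* a fitted slope $E_1 \notin (0,1)$, zero signals or non-finite inputs
  never raise — the voxel is flagged invalid and masked, because clamping
  out-of-range fits would bias profile statistics;
* air is pre-masked where the per-voxel maximum signal falls below 5% of
  the robust (99th-percentile) maximum. No masking rule is part of the
  measurement definition itself; this one simply keeps background voxels
  out of every downstream statistic.

Nominal flip angles are taken as true (no B1 transmit correction); this is
a documented limitation, consistent with how such gel measurements are
usually analyzed at 3 T with small vials near isocentre.

## Calibration and the G-value

`roi_mean_r1()` pools valid voxels of a circular ROI (default φ10 mm) by
voxel-centre inclusion — the simplest reproducible membership rule at 1 mm
resolution; partial-volume weighting would change ROI means by well under
the ROI noise. `fit_linear_calibration()` performs the (by default
unweighted) OLS fit of ROI-mean R1 against Fe³⁺ concentration or entrance
surface dose.

The slope standard error deserves a note. With five calibration levels, a
residual-based OLS slope SE has three degrees of freedom, and the pivot
(slope − truth)/SE is t₃-distributed: a ±3 SE interval then covers the
truth only ~94% of the time no matter how good the data. The per-point ROI
statistics carry the measurement error directly, so when every point
provides `r1_sd` and `n_voxels` the package propagates
$SE_i = \mathrm{sd}_i/\sqrt{n_i}$ through the OLS weights instead, giving
an approximately normal pivot and the coverage one expects of a ±3 SE
band (~99.7%). The residual-based SE remains the fallback for bare
`(level, r1)` tables, and an inverse-variance weighted fit is available as
an option.

The radiation chemical yield is the plain unit-bookkeeping ratio

$$G(\mathrm{Fe^{3+}})\ [\mu\mathrm{mol\,J^{-1}}] =
  \frac{\text{dose sensitivity } [\mathrm{s^{-1}kGy^{-1}}]}
       {\text{relaxivity } [\mathrm{s^{-1}mM^{-1}}]\ \cdot\
        \rho\ [\mathrm{kg\,L^{-1}}]},$$

with independent relative errors combined in quadrature when supplied. The
default density is 1.007 ± 0.004 kg/L (the literature value prints the
uncertainty as "± 4", which can only be a typo for ±0.004; the package
stores the latter). The relaxivity that enters the published worked
example (5.7 s⁻¹mM⁻¹) is treated as a given scalar input: it is a
measured property of a specific gel batch, not a number the pipeline can
re-derive.

## Depth-dose analysis

`delta_r1()` subtracts the control (unirradiated) map from the irradiated
map, keeping the intersection of the validity masks and preserving
negative noise excursions. `extract_depth_profile()` walks the beam axis
(z, the slowest array axis, by convention overridable) at a chosen
in-plane position; for an odd width n > 1 it averages the in-plane n×n
neighbourhood per depth and reports the neighbourhood SD. The literature
phrase "averaging the adjacent three, five, and seven slices" is ambiguous
between in-plane neighbourhoods and slice-direction averaging; the package
implements the n×n boxcar as the default and a slice-direction-only mode
(`mode = "slices"`) as the alternative, asserting neither as *the*
original procedure.

Depth 0 is the first valid gel voxel along the axis (requiring two further
valid voxels, to ignore isolated noise voxels). Because band-limited
reconstruction smears the strong gel/air entrance edge into the adjacent
air voxel — and because the VFA fit is invariant under a common scaling of
the per-angle signals, that smeared voxel fits to a perfectly plausible
gel R1 — the detected origin can sit one voxel shallow of the geometric
gel surface. The depth origin therefore carries an intrinsic ±1 voxel
uncertainty; peak-depth contracts in the tests are stated accordingly.

`find_bragg_peak()` takes the global maximum with ties broken toward the
shallower depth (the physically conservative choice for a distal edge);
3-point parabolic refinement is available but off by default.
`pdd_normalize()` anchors 100% at the mean over a 10–20 mm entrance
window rather than the literal first sample, which is contaminated by
entrance ringing and meniscus effects. `compare_profiles()` interpolates
gel and reference (e.g. ionization-chamber) curves linearly onto the
intersection of their depth ranges at the gel pitch — no extrapolation,
no smoothing. `image_quality()` reports CV% = 100·σ/mean over an ROI and,
mirroring that definition, SNR = mean/σ over the same ROI (the source
analyses print SNR without a formula; this is the matching choice).

## The synthetic phantom

The generator's defaults *are* the study conditions: a φ35 × 78 mm gel
vial at 1 mm isotropic resolution on a 64 × 64 × 96 grid (the published
acquisitions use a 256 mm field of view, most of which is air; the
simulation grid crops to the vial with generous margins), entrance
sensitivity 1.08 s⁻¹kGy⁻¹, peak sensitivity 3.84 s⁻¹kGy⁻¹, entrance
surface doses 150–600 Gy, magnitude noise calibrated to a 3.7% R1-map CV,
and a 10 × 10 mm square field with a Bragg peak at 48 mm depth.

**Beam.** The depth-dose curve is a deliberately simple parametric
stand-in — a linearly declining plateau, a Gaussian peak, and a
sigmoid-gated fragmentation tail of 10% of the local plateau dose dying
out within ~3 peak-widths past the peak. The curve is *measured, never
modelled,* in the source work, and Monte-Carlo transport is explicitly out
of scope, so the functional form is a repository construction with the
right qualitative anatomy. Values not fixed by any source were chosen
once, as plausible for a 290 MeV/u carbon pencil beam behind a range
shifter: peak-to-entrance dose ratio 3.0, peak width σ = 2.5 mm, plateau
decline 0.3%/mm, lateral penumbra σ = 1 mm growing at 0.08 mm/mm beyond
15 mm proximal of the peak, background gel R1 0.65 s⁻¹, M0 = 1000 a.u.
The Gaussian's centre and amplitude are solved (fixed-point iteration) so
that the curve's true maximum sits exactly at the nominal peak depth with
the requested ratio — a naively centred Gaussian on a sloped background
shifts the argmax by a few tenths of a millimetre. Lateral profiles are
the analytic Gaussian-blurred square field, so lateral flux is conserved
at every depth by construction.

**Sensitivity.** The depth-dependent sensitivity s(z) interpolates
linearly from the entrance value (up to 3 peak-widths before the peak) to
the peak value, constant after — an empirical encoding of the measured
entrance/peak slope difference, with no LET model behind it.
`dose_from_delta_r1()` inverts exactly this model.

**Acquisition.** The ideal R1 image is rendered 8× oversampled in the
(y, z) frequency/phase-encode plane — the plane that contains the beam
axis, as in a sagittal acquisition — converted to per-angle SPGR signals,
and truncated per x-slice to the acquisition matrix by central k-space
cropping (`apply_kspace_truncation()`). A linear phase in k-space aligns
the decimated samples with the voxel-centre convention, so reconstructed
and ground-truth volumes share one coordinate system. 8× oversampling
leaves residual discretization far below the ~9% Gibbs amplitude. The
slice direction (x) is not truncated, matching where ringing arises for
the actual matrix. Zero-filled ("source"-grid) output is provided for
measuring ringing amplitudes, because on the decimated grid the apparent
overshoot depends on edge/sample alignment.

**Noise.** Magnitude images get Rician noise — the magnitude of the
signal plus complex Gaussian channel noise — because the pipeline
consumes magnitude MR data. The quantity the study conditions fix is not
the channel σ but the *resulting R1-map CV* (3.7%), so σ is calibrated by
a documented pre-run: the delta-method gradient of the two-point VFA
estimator at the background-gel signal level converts a target R1 SD into
a signal σ, and the spatial SD that deterministic ringing already
contributes inside the reference ROI (measured on the noiseless control
reconstruction) is subtracted in quadrature. At these SNRs (≳ 50) the
Rician and Gaussian regimes are indistinguishable for the calibration.
A pleasant exact property falls out of the uniform control vial: ringing
rescales both flip-angle signals by the same spatial pattern, the VFA
ratio cancels it, and the fitted control R1 is exact to floating-point
precision wherever valid — the test suite asserts this.

**What the generator does not emulate.** B0/B1 inhomogeneity, imperfect
spoiling, slice-profile effects, gel chemistry (radiolysis kinetics,
temperature dependence), nuclear fragmentation spectra, and scanner raw
formats. Passing tests therefore demonstrate the *analysis chain* is
correct and well-conditioned under realistic noise and sampling artifacts;
they say nothing about chemical reproducibility of a physical gel batch.

## Problem sizes and seeds

All stochastic fixtures are seeded and bit-reproducible. The test suite
exercises a reduced 16 × 32 × 48 phantom (4× oversampling, peak at 24 mm)
for fast unit checks and the full default 64 × 64 × 96 phantom for the
end-to-end dose-series checks; the calibration-replicate study runs 1000
seeded noise realizations of a five-level Fe³⁺ series, using an
ROI-restricted noise path that is exact because the VFA fit is
independent per voxel and the noise i.i.d. The acceptance script averages
the dose-response R² over 10 noise seeds of the full-size series.

## Known limitations

* No B1 correction; nominal angles assumed exact.
* The depth origin of profiles carries ±1 voxel uncertainty (entrance-edge
  smearing, above).
* The beam model is qualitative; its lateral-spread law in particular is
  configurable but not asserted as physics.
* Spin-echo acquisition is not simulated; SE data enter only as tabulated
  comparison values.
* R² is reported as the OLS coefficient of determination, identical to
  the squared Pearson correlation for these simple linear fits.
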