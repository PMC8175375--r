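---
title: "Quantifying bolus CEUS cine loops: models, parameters and design choices"
author: "ceusquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bolus CEUS cine loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceusquant)
```

## The measurement model

Contrast-enhanced ultrasound with a microbubble bolus produces a cine
loop in which each pixel's grey level tracks the local intravascular
microbubble concentration. `ceusquant` treats the clip after scanner
processing as an ordered stack of 8-bit grayscale frames with a known
frame rate; everything upstream of that — beamforming, harmonic contrast
sequences, log compression, colorization — is taken as given. Three
assumptions follow:

1. **Linearity within an ROI is not assumed** — only that the *mean*
   grey level over a region is a usable perfusion index. All comparisons
   are within-modality and mostly within-clip (artery normalization),
   so monotone scanner compression affects all tissues alike.
2. **Stationary geometry.** ROIs are drawn once and applied to every
   frame. Clips where the probe or tissue moved are detected by the
   motion score and flagged, never corrected: motion correction is out
   of scope, so a flagged clip should be excluded by the analyst.
3. **8-bit quantization** is the native resolution. Intensities are
   reported on the `[0, 1]` scale (mean grey ÷ 255) so that peak
   enhancements are commensurable across clips and with published
   cohort tables whose "arbitrary units" sit in the same 0.17–0.59
   range for white matter through artery.

### Per-ROI metrics

With `TIC(t_k)` the mean masked intensity at frame `k`:

- **Peak enhancement** is the curve maximum; ties break to the
  *earliest* maximal frame, a deterministic choice that reads "peak" as
  first attainment. On 8-bit data the frames around the maximum often
  round to the same grey level (a quantization plateau), so peak *times*
  carry no sub-plateau precision: at the default arterial kinetics the
  plateau spans several tenths of a second, and the earliest-frame rule
  reports its left edge.
- **AUC** is the trapezoidal integral of the TIC over *seconds*, not
  frames, making it invariant to the frame rate. No baseline is
  subtracted by default — the raw integral of the curve — because
  recordings that start after injection have no defensible baseline;
  `tic_auc(baseline_subtract = TRUE)` integrates
  `max(TIC − baseline, 0)` for users who want the enhancement-only
  integral.
- **Normalized AUC** divides a tissue's AUC by the same clip's arterial
  AUC. Acquisition durations differ between patients; the ratio cancels
  duration (and any clip-wide gain) to first order. The artery's own
  ratio is identically 1, so it is reported as missing and excluded
  from cohort testing.
- **Arrival** is the first run of `min_consecutive` frames exceeding
  `baseline + k_sigma · sd(baseline window)`. This rule is this
  package's operational definition of "first detectable signal";
  defaults (window 10 frames, `k_sigma = 4`, run length 3) are a
  conventional low-false-positive choice: under Gaussian baseline noise
  a single 4-sigma exceedance has probability ≈ 3·10⁻⁵, and requiring
  three in a row makes spurious arrivals negligible over clip-length
  baselines. All three constants are exposed. The rule time-stamps
  *detectability*, not physiologic onset: a bolus that crosses the
  threshold slowly is dated at the crossing. When no run exists (flat
  curve, or a recording started after the bolus) arrival is absent,
  phase segmentation refuses with an explicit error, and PE/AUC are
  still computed.
- **Phase segmentation** partitions the clip into baseline, wash-in,
  peak, early wash-out and late wash-out. The early/late wash-out
  boundary is the first frame where enhancement falls below
  `washout_fraction` (default 0.5) of peak-over-baseline — the
  half-enhancement point, chosen because it is well defined for any
  unimodal decay; the published phase nomenclature names the phases
  without quantitative boundaries, so the fraction is configurable. If
  the curve never falls below the cut, early wash-out runs to the last
  frame and late wash-out is empty.

### Cohort statistics

Per-tissue groups are summarized as count, sum, arithmetic mean and
*sample* variance (n − 1). Whether published cohort variances used the
sample or population convention cannot be determined without the raw
values; the convention is declared so the comparison is interpretable.
Tissue contrasts use two-sided paired t-tests (`stats::t.test`,
`paired = TRUE`) — "brain" in the standard contrasts means the
white-matter reference ROI, since grey matter is not reliably measurable
in intraoperative fields. Patients missing one side of a pair are
dropped from that comparison only (pairwise-complete deletion), so a
cohort with one unusable tumor measurement tests artery–brain on all
patients and the tumor contrasts on one fewer. P-values are deliberately
unadjusted: the three contrasts answer one ordered hypothesis, and the
command-line tool prints a note whenever more than one comparison runs.

## The synthetic generator

`generate_cine()` is the package's test bed and makes no claim to
acoustic realism. Each compartment's mean curve is a **gamma-variate**
indicator-dilution kernel with an additive saturating tail,

    f(τ) = (1 − q) · τ^α e^{α(1−τ)} + q · (1 − e^{−τ}),
    τ = (t − onset) / time_to_peak,

scaled into `[baseline, baseline + amplitude]`. The gamma-variate factor
peaks at exactly `τ = 1`, giving closed-form oracles for peak location;
the tail `q` creates the persistent late-wash-out plateau that slow
tissues show. The default scene encodes an intraoperative cerebral bolus
passage:

| parameter | artery | tumor | white matter | why |
|---|---|---|---|---|
| onset (s) | 25 | 26 | 27 | arterial arrival 20–30 s post-injection; ~1 s stagger between structures |
| time to peak (s) | 7 | 8 | 8 | arterial wash-in lasting roughly 6–8 s |
| amplitude | 0.57 | 0.43 | 0.165 | lands peak enhancement near the published group means 0.584 / 0.436 / 0.175 |
| shape α | 3 | 2.5 | 2.5 | artery sharpest |
| tail q | 0.05 | 0.10 | 0.15 | white matter faintest but most persistent |

with a 45 s, 10 Hz, 64×64 clip (45 s is a typical accepted clip length),
background level 0.02, and mutually disjoint geometries (vertical
arterial band, circular tumor, white-matter slab) so extracted TICs are
uncontaminated. Speckle is **multiplicative and unit-mean**: each
pixel/frame value is scaled by `1 + σ·(R − 1)` with `R` a unit-mean
Rayleigh draw and `σ = noise_sigma` (default 0.15). Unit-mean noise
leaves the expected TIC equal to the clean curve at every noise level,
so parameter-recovery tests have unbiased targets; Rayleigh-derived
factors echo the amplitude statistics of fully developed speckle without
modelling the point-spread function, attenuation with depth, or
pseudoenhancement — none of which the generator emulates, so passing
tests say nothing about those artifacts on real data.

`generate_cohort()` draws per-patient metric vectors directly: tissue
value = mean + sd · (√ρ·z + √(1−ρ)·ε) with a shared per-patient factor
`z`, giving cross-tissue correlation ρ, then clips to `[0, 1]`. Default
means and sds are the published 19-patient group averages and root
variances. The coupling default **ρ = 0.8** is back-calculated rather
than guessed: a paired artery–tumor contrast reported at p ≈ 1.1·10⁻⁴
with n = 19 implies |t| ≈ 4.8 and hence sd(difference) ≈ 0.134, which
with group sds 0.219 and 0.214 requires a cross-tissue correlation near
0.8 — a strongly coupled cohort in which a well-perfused patient is
bright in every tissue. Two consequences are documented because they are
easy to trip over:

- **Clipping bias.** With the white-matter mean at 0.175 and sd ≈ 0.184,
  clipping at 0 truncates roughly a sixth of the lower tail and raises
  the realized mean by about +0.017. Mean-recovery tests therefore
  compare against the closed-form mean of the clipped normal, not the
  nominal mean — the correct expectation for the generator as defined.
- **Power.** At these defaults the three paired peak-enhancement
  contrasts on n = 19 are all significant at 0.05 in ≈ 99% of cohorts,
  and the artery > tumor > white-matter ordering of group averages is
  recovered essentially always; the type-I error of the paired test on
  null cohorts calibrates to 5% ± 2%.

## Numerical and convention choices

- **Coordinates** are 0-based, row-major pixel indices; a pixel's
  reference point is its center. One convention, declared once, used by
  the rasterizer, the JSON schema and the oracles.
- **Rasterization boundaries are inclusive**: a pixel center exactly at
  circle radius or on a polygon edge belongs to the ROI (even-odd rule
  plus an explicit on-edge test). Deterministic and testable against an
  exhaustive point-in-shape oracle. Partial-pixel weighting is not
  offered; masks are binary.
- ROIs partially outside the frame are clipped silently — small
  placement error should not kill an analysis — but an ROI with no
  pixel inside the frame is an error, as is any ROI that rasterizes to
  zero pixels.
- **RGB → grayscale** uses ITU-R BT.601 luma weights (0.299, 0.587,
  0.114), rounded half-up; the conventional choice when the upstream
  colorization is opaque. Single-channel input outside `[0, 255]` is
  min–max rescaled (a constant stack maps to zeros, the documented
  degenerate case); input already in range passes through unchanged.
- **Thresholding** pushes pixels ≥ upper to 255. The symmetric lower
  cut (≤ lower → 0) is this package's extension, included so one
  operation serves both highlighting directions; the operation is
  idempotent and order-stable (upper rule first).
- Integration uses `pracma::trapz`; the trapezoid rule is exact on the
  piecewise-linear curves the tests use as oracles.
- Cines are exchanged as multi-page 8-bit grayscale TIFF — lossless,
  open, bit-exact round trip — never as lossy video. The frame rate is
  caller-supplied metadata everywhere, including the CLI, because
  scanner exports report it inconsistently (acquisition and display
  rates can differ by a factor of two in the same study).

## What the tests establish

The suite validates the pipeline at sizes a laptop handles in seconds:
rasterization and TIC extraction against brute-force per-pixel oracles
on frames up to 64×64 and 50 random cine/ROI instances; the
generator/analyzer closed loop (noiseless cines reproduce their model
curves within half a grey level everywhere); arrival timing within 3
frame periods of a sharp simulated onset at SNR 20 over 100 replicates
(a slow onset is dated later by construction — see the arrival rule
above); 100-cohort power and 2000-cohort type-I calibration at n = 19.
These sizes were chosen as the smallest that make the Monte-Carlo
margins meaningful; they are properties of the synthetic model, and
transfer to real recordings only insofar as the model's assumptions
(stationary geometry, unimodal bolus, unit-mean speckle) hold there.

## Known limitations

- No curve fitting: wash-in rate, time-to-peak or gamma-variate
  parameter estimates are out of scope; metrics are read off the raw
  (optionally moving-average smoothed) curve.
- No attenuation or pseudoenhancement compensation; deep or shadowed
  ROIs will bias PE and AUC in ways the package cannot see.
- Motion is flagged, not corrected; the flag threshold (25 grey levels
  mean absolute difference) suits abrupt probe motion, not slow drift.
- Recordings that begin after contrast arrival have no baseline: arrival
  is reported absent and phase segmentation is unavailable, while PE,
  AUC and normalized AUC remain valid.
- Quantized peak times are plateau-resolution, as discussed above.
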