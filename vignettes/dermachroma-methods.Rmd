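---
title: "Quantifying radiation dermatitis with colour-space parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiation dermatitis with colour-space parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermachroma)
```

## The measurement problem

Acute radiation dermatitis — the erythema and darkening of skin exposed
during whole-breast radiotherapy — is conventionally graded by eye on
ordinal physician scales (RTOG 0–4). Such scores are subjective, coarse,
and insensitive to the mild (grade ≤ 1) reactions that dominate modern
fractionation schedules. `dermachroma` implements an objective
alternative: close-up skin images of the irradiated and the contralateral
(control) breast, taken at four sites around the nipple and at four time
points across the treatment course, are reduced to twelve colour-space
parameters whose longitudinal trajectories and dose dependence can be
tested statistically.

The twelve parameters are the channel means of four colour models:

* **RGB** — R, G, B on the 8-bit 0–255 scale;
* **HSV** — hue, saturation, value on [0, 1] (hexcone model);
* **CIE L\*a\*b\*** — lightness 0–100, red–green a\*, yellow–blue b\*;
* **YCbCr** — BT.601 *studio-swing* luma/chroma, Y in 16–235 and Cb, Cr
  in 16–240.

Erythema raises a\*, R, S, V and Cr and lowers G, H and L\*; this sign
pattern is what the analysis exploits.

## Colour conversions

The conversions are authored in the package rather than delegated to a
graphics library, because their dialect is part of the measurement
definition; the test suite verifies them against independently coded
formula evaluations and against the R graphics stack.

* **HSV.** V = max(r,g,b); S = (max−min)/max for max > 0, else 0; H is
  the hexagonal hue angle scaled to [0, 1) with 1 wrapped to 0. The hue
  of an achromatic pixel is undefined in the mathematics; we define it as
  0 so that ROI averaging stays deterministic.
* **L\*a\*b\*.** The imaging device stores sRGB, so the pipeline applies
  the sRGB inverse gamma, the sRGB→XYZ matrix under the D65 illuminant,
  white-point normalization, and the CIE cube-root function with its
  linear segment below (6/29)³. The reference white is taken as the row
  sums of the conversion matrix — the D65 white implied by the sRGB
  primaries — so that RGB white maps to exactly L\* = 100, a\* = b\* = 0.
  No other gamma or white point is supported; ICC profiles and chromatic
  adaptation are out of scope.
* **YCbCr.** The stated 16–235 / 16–240 nominal ranges fix the BT.601
  studio-swing affine transform; full-swing (JPEG) YCbCr is deliberately
  not used. Values are kept in double precision — they are never
  re-quantized to bytes before averaging.

## Region-of-interest reduction

Each image is reduced to one twelve-parameter vector over a circular ROI
(design radius 300 px at the device's native 1624 × 1212 px over
1 × 1 cm). Pixel coordinates are 0-based and a pixel belongs to the disc
iff the Euclidean distance from its integer coordinate to the centre
(`(W−1)/2`, fractional for even dimensions, keeping the mask symmetric)
is ≤ the radius. Every member pixel is converted first and the per-pixel
parameters are then averaged — *convert-then-average*. For the nonlinear
models the order matters, and a regression test pins it down. Two caveats
are documented rather than "fixed": hue is averaged arithmetically like
the other parameters (improper for circular data near the red
wraparound, but it is what the matrix-mean definition prescribes, and
skin hues sit safely away from the wraparound), and no pixels (e.g.
saturated ones) are excluded from the mean. Images smaller than the
design radius get the largest inscribed disc so that small synthetic
images run fast; a strict mode errors instead.

## Dosimetry

Skin dose is measured on the first fraction with nanoDot OSLD chips,
three per site, averaged per site, and averaged again into the patient
mean. The package ships the 20-patient published dose table as a plain
CSV; `osld_dose_table()` re-validates every printed mean against its four
site doses (±0.05 cGy, the print rounding) on load. `site_extremes()`
reproduces the table's dose geography — the inner site is the row
minimum in 14 of 20 rows and the row maximum falls on the upper or lower
site in 17 — with ties credited to every tied site (the printed table has
none).

## Statistical procedures

All tests operate on the per-patient value of a parameter: the four site
measurements of one breast and time point are averaged first, because
patients, not sites, are the repeated unit. (A site-level pairing mode
exists for sensitivity analysis.)

* **Two-way repeated-measures ANOVA** with both factors (breast, time)
  within-subject. Each effect is tested against its own
  subject-interaction error stratum via orthonormal contrast scores.
  For multi-level effects, Mauchly's test (Box's two-term chi-square
  series, matching the major statistics packages) is run on the contrast
  covariance; only when it rejects at 0.05 are the degrees of freedom
  multiplied by the Greenhouse–Geisser ε computed from the eigenvalues of
  that covariance. Degenerate strata (no variation) report F = 0, p = 1.
* **Wilcoxon signed-rank** for irradiated-vs-control comparisons at each
  time point: zero differences discarded, midranks of |d|, W = min of the
  signed rank sums, exact two-sided p for n ≤ 15 without ties, otherwise
  the normal approximation with tie and continuity corrections. The
  significance level is Bonferroni-adjusted; the default family of m = 3
  comparisons gives 0.05/3 ≈ 0.0167. m is configurable because the choice
  of family (three post-baseline time points vs. three pairwise
  contrasts) is a study-design decision, not a mathematical one.
* **Spearman rank correlation** for dose–response (per parameter, at the
  three post-baseline time points, against the patient mean dose) and for
  early-vs-final prediction. Midranks handle ties; the two-sided p comes
  from the t approximation on n−2 df, the behaviour of the large
  statistical suites this analysis mirrors at n = 20. An exact
  permutation-enumeration mode (n ≤ 8) exists and is held against a
  brute-force oracle in the tests. The dose-correlation report masks
  cells with p ≥ 0.05, as such tables are conventionally printed; the
  unmasked values are always returned alongside.

## The synthetic cohort

Clinical images cannot ship with a package, so the generator produces a
cohort with the statistical structure the analysis assumes, and it is
first-class, tested code. Per patient: a baseline skin tone drawn in
L\*a\*b\*; four site doses; and 32 uniform-base images (2 breasts × 4
sites × 4 time points) with i.i.d. Gaussian pixel texture. The irradiated
breast's colour is shifted additively in a\* by
`dose_slope_a × site dose × time_profile[t]`, with fractions `frac_b`
(+0.38) and `frac_L` (−0.11) coupling the shift onto b\* and L\* —
erythema is physiologically a redness shift with mild darkening. The
control breast gets only a small zero-mean drift (sd 0.3 Lab units).
Colours go to RGB through the package's own inverse L\*a\*b\* path, so a
noise-free render inverts back to its constructed Lab values to 1e-6,
which the tests exploit.

Defaults were fixed once to emulate the study conditions:

* baseline Lab centred at (72, −1.2, 20.2) — the Lab of the cohort's mean
  baseline skin colour (RGB ≈ 189, 176, 140);
* `dose_slope_a` = 0.031 per cGy and `time_profile` = (0, 0.36, 0.72, 1),
  so the mean a\* rises from ≈ −1 to ≈ +6 across the course at the
  observed ≈ 235 cGy mean skin dose, reproducing the reported
  trajectory's scale;
* site doses sampled in the observed 186.7–284.0 cGy range with a shared
  per-patient dose level plus site-specific windows (inner lowest,
  upper/lower highest), because measured tables show whole rows running
  high or low together;
* between-patient baseline chroma spread kept modest (a\* in
  [−1.8, −0.6]) so that the dose-driven redness is detectable at n = 20 —
  the effect-to-baseline ratio implied by the reported dose correlations
  (r ≈ 0.5–0.6), not the full between-patient variance of real skin
  tone;
* pixel noise sd 6 counts; image size 128 × 128 px (the native
  1624 × 1212 is available via `image_size`), with the ROI auto-shrunk.

RTOG grades are derived by thresholding the final a\* shift into {0, 1},
consistent with a cohort that never exceeds grade 1, and are carried as
metadata; on grade-constant data the RTOG correlation is undefined and
reported as such rather than invented.

What the generator does **not** emulate: real skin texture (pores, hair,
specular highlights), illumination drift, patient repositioning, response
heterogeneity beyond the linear dose model, and desquamation (grades
≥ 2). Passing tests therefore show that the pipeline recovers the
structure it assumes, not that the model is biologically complete.

## Numerical and design choices

* Conversions accept fractional channel values in [0, 255]; 8-bit
  quantization happens only when images are written to disk.
* One master seed expands into per-patient and per-image substreams (a
  31-bit string hash of patient/breast/site/time), so any subset of a
  cohort regenerates identically.
* Simulation scale: the calibration suites run 2,000 null replicates of
  each test at n = 20 and 200 null cohorts with 16 × 16 px images (the
  ROI parameter reduction makes image size irrelevant to the null
  distribution of the patient-level statistics); the recovery check runs
  one n = 20 cohort at the default 128 × 128.
* Under the null the Spearman t-approximation rejects at a measured rate
  of ≈ 0.0498 at n = 20, so the fraction of significant dose-correlation
  cells in a dose-effect-free cohort sits at the nominal 5% by
  construction — the calibration suite checks it stays there.
* The exact Wilcoxon tail uses the base-R signed-rank distribution;
  the enumeration over sign assignments lives in the test oracle,
  keeping the two routes independent.

## Known limitations

* Arithmetic hue averaging is improper for circular data; acceptable
  here only because skin hues cluster near 0.1, far from the wraparound.
* The L\*a\*b\* dialect is fixed to sRGB/D65; device-specific colour
  calibration is out of scope.
* The Spearman t-approximation is slightly anti-conservative in the
  extreme tails at small n; the exact mode covers n ≤ 8 only.
* The generator's linear dose–response with shared slope is a
  deliberately minimal model: it supports calibration and recovery
  testing, not biological inference.
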