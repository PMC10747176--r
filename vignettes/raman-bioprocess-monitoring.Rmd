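---
title: "Monitoring nitrogen-starved microalgal cultures from Raman spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring nitrogen-starved microalgal cultures from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramalgae)
```

## Scope and model of the data

`ramalgae` analyses time series of Raman spectra acquired from a
microalgal culture over a production run. The physiological narrative the
chain is built to resolve is the nitrogen-starvation switch of green
microalgae: during balanced growth the spectra are dominated by
resonance-enhanced carotenoid bands (~1157, ~1524 cm⁻¹) and chlorophyll
(~988 cm⁻¹); once nitrate is exhausted the cells degrade pigments and
channel carbon into storage lipids, so triacylglycerol (~1750 cm⁻¹),
CH-stretch (~2850–2970 cm⁻¹) and unsaturation (~1660, ~3008 cm⁻¹) bands
rise while the pigment bands collapse.

A measured spectrum is modelled as

> signal(x) = Σ_b a_b · peak(x; c_b, w_b) · (1 + ε) + background(x) + noise(x)

with per-band amplitude a_b following a day-indexed trajectory, one
multiplicative scatter factor ε per spectrum (focus, turbidity, biomass
density — the effect SNV removes), a broad smooth fluorescence
background, and additive white noise. Every pre-processing stage is the
inverse of one of these nuisance terms; the analysis stages then work on
what remains.

## The synthetic generator

No spectra of this kind are publicly deposited, so the package's claims
are validated against its own seeded generator, which emulates the
statistical structure above:

* **Schedules.** `default_config("lab")`: 50 spectra once daily for 36
  days (1800 scheduled spectra). `default_config("pilot")`: four sessions
  a day, six hours apart, 50 spectra each, for 14 days (2800). Real
  campaigns of this design yield slightly fewer spectra than scheduled
  (acquisition drop-outs); the generator emulates the nominal schedule.
* **Bands.** All thirteen assigned bands (479–3008 cm⁻¹), Gaussian by
  default (Lorentzian selectable); line shapes are not resolvable at the
  10 cm⁻¹ instrument resolution, and Gaussians permit closed-form checks.
  Widths 22–26 cm⁻¹ FWHM keep neighbouring CH-stretch bands resolved as
  local maxima.
* **Amplitude trajectories** are piecewise-linear through a small set of
  (day, amplitude) nodes. Pigment bands rise from a moderate inoculation
  level (the inoculum comes from a grown pre-culture) to an early plateau
  around day 3, hold until the nitrogen-depletion day (pilot day 8, lab
  day 6), then fall steeply over about two days — nitrogen-starvation
  chlorosis is fast — and stay low; the lab variant declines gradually
  over the long starvation and ends with a slight carotenoid re-rise.
  Storage-lipid bands stay flat until depletion and then rise linearly.
  A single-breakpoint ramp was deliberately rejected: it spreads each
  phase along PC1 and erases the two-cluster (pigment-rich vs lipid-rich)
  score structure that real nitrogen-switch campaigns show; the
  plateau–collapse shape restores it.
* **Background.** A quadratic polynomial in the scaled wavenumber plus a
  decaying exponential (defaults 8 + 6u − 5u², amplitude 30, decay
  1/800 cm; peak amplitudes 0.3–8), emulating chlorophyll fluorescence
  that dominates raw intensities — with these defaults ~97 % of raw
  intensity is background, as in fluorescence-dominated practice.
* **Noise.** Additive white Gaussian noise (default sd 0.16 ≈ 2 % of the
  largest peak) and multiplicative per-spectrum jitter (sd 0.05) applied
  to the band component.
* **Axis.** 300–3100 cm⁻¹ at 2 cm⁻¹ steps — finer than the 10 cm⁻¹
  instrument resolution so that 25-point smoothing windows span ~50 cm⁻¹,
  a meaningful width.

`monotone_kinetics_config()` is a validation variant with strictly
monotone trajectories (1524: 8→2; 1660: 1.5→4; 1444 constant; everything
else frozen), used to test kinetics recovery where rank correlations
against ground truth are well-defined over the whole run.

What the generator does *not* emulate — cosmic-ray spikes, wavenumber
miscalibration, detector nonlinearity, exposure-time switching, sampling
drop-outs — bounds what green tests mean: they demonstrate correctness of
the chain under the stated statistical model, not robustness to every
artefact of a real instrument.

## Pre-processing chain

Order: crop → baseline → smoothing → SNV, applied per spectrum.

**Cropping** retains 350–1800 and 2800–3050 cm⁻¹ (inclusive endpoints).
The two windows stay concatenated in one vector; all later stages detect
the gap (axis step > 2.5× the median step) and treat each contiguous
segment independently — a hull or smoothing window spanning the 1000 cm⁻¹
gap would be meaningless.

**Concave (bent) rubberband baseline.** The classic rubberband baseline
is the lower convex hull of the spectrum; it cannot follow a background
with concave curvature. Per iteration (10 by default) we therefore
compute the hull of the working spectrum in a *bent frame*,
w − tan(θ)·A·(x−x₀)(x₁−x)/((x₁−x₀)/2)², with θ = 64° and A the working
intensity range, then interpolate the *original* intensities linearly
between the hull touch points and subtract. Bending the frame is
equivalent to bending the rubberband upward, so concave backgrounds
become touchable; as θ → 0 the procedure is exactly the classic
rubberband (verified against a brute-force O(n²)-chord hull oracle).
Because the bending term is concave and zero at the segment ends, the
subtracted estimate never exceeds the spectrum: the corrected signal is
non-negative by construction, lines and constants are their own baseline,
and corrected + baseline reconstructs the input bitwise. On simulated
campaigns with the default background the recovered baseline is within
~3.6 % RMS of the truth (in units of the largest peak amplitude), noise
included.

**Savitzky–Golay smoothing**: moving least-squares polynomial fit, window
25 points, degree 2, two passes. Degree 2 is the standard chemometrics
default (the window count is the conventionally quoted parameter; two
passes read as two sequential applications of the same filter). Interior
points use the symmetric central kernel; the 12 points at each segment
edge are fitted on the truncated one-sided window, which preserves the
polynomial-reproduction property right up to the segment ends. The
implementation is checked against a per-point `lm()` oracle.

**SNV** standardises each spectrum to zero mean and unit sample standard
deviation (n−1), computed jointly over all retained points of that
spectrum — not per segment, which would decouple the fingerprint and C–H
regions. Constant spectra are rejected as degenerate. SNV removes the
multiplicative jitter exactly: two spectra differing by a positive scale
factor preprocess to the same result.

## Quality control

All-pairs Pearson correlation of the pre-processed spectra, ordered by
(day, session, replicate); symmetry and the unit diagonal are enforced
exactly. "Repeatability" of a day is the mean ± sd of its m(m−1)/2
unordered within-day pairs — self-pairs are excluded since their perfect
correlations would bias the summary — and is a within-group pairwise
statistic, not a lag autocorrelation. Similarity-to-reference correlates
each day's spectra against all reference-day spectra (day 0 by default).
Sessions within a calendar day are pooled by default (`pool_sessions =
FALSE` keeps them separate). The QC layer reports; it does not filter
outliers.

## Band kinetics

Band "intensity" is the maximum within ±8 cm⁻¹ of the assigned center —
robust to calibration drift up to the half-window at 10 cm⁻¹ resolution —
with trapezoidal area integration available (`stat = "area"`). Intensities
are read from SNV-normalized spectra, so they are dimensionless and may
be negative; ratios remain meaningful because both bands sit on the same
normalized scale. Ratios are computed per spectrum and then averaged per
day (never as ratios of day means), so common per-spectrum factors
cancel. Day means were chosen as the kinetic summary (sessions pooled);
per-session traces are obtainable by filtering the metadata.

## PCA and the day-group test

PCA is computed by SVD of the column-mean-centered matrix, without
variable scaling (SNV already standardises rows); explained fractions are
σᵢ²/Σσ². Signs are fixed by requiring each loading's largest-magnitude
element to be positive, making results reproducible and
permutation-invariant. Any component triple can be exported for 3-D score
plots.

The Kruskal–Wallis test runs on all spectra (not day medians) grouped by
culture day, on the first PC score. Ranks use midranks; H carries the tie
correction 1 − Σ(t³−t)/(N³−N); p comes from the χ² approximation with
(groups − 1) df. The post-hoc procedure is a Dunn-type z on mean-rank
differences with the matching tie correction, Bonferroni-controlled over
the pairs actually compared — adjacent days by default (13 pairs for a
14-day run), all pairs optionally. Monte-Carlo checks: type-I error
0.03–0.07 at α = 0.05 under the null (5 groups × 20), and ≥ 0.9 power to
flag the programmed breakpoint pair for a 1-sd location shift with 50
observations per day — one acquisition session's worth, a quarter of the
full pilot per-day count.

## Quantification arithmetic

The pigment equations take methanol-extract absorbances, subtract the
750 nm turbidity from every channel (A₄₈₀, A₆₅₂, A₆₆₅ alike), and scale
by extract volume (1.5 mL default) over biomass volume. Absorbance
combinations outside the formulas' calibration domain can yield negative
concentrations; these are reported with a warning, never clipped.
Total lipids are extract mass over sample volume. Optical densities
measured at ≥ 0.8 are outside the spectrophotometer's linear range and
carry a validity flag rather than an error.

## Numerical choices and degenerate inputs

* Hull computation: Andrew's monotone chain; collinear interior points
  are dropped (the interpolated baseline is identical).
* Segment detection: axis step > 2.5× median step starts a new segment;
  segments need ≥ 3 points (baseline) and ≥ window points (smoothing).
* A flat working residual (range 0) reduces the bent frame to the plain
  hull, so constants resolve in one iteration.
* Reconstruction is made bitwise-exact by deriving the reported baseline
  as input − corrected after the iterations.
* Ties in ranks use midranks everywhere; the KW tie term and the Dunn
  variance share the same tie table.
* Seeding: `simulate_spectra()` seeds from its config and restores the
  caller's RNG state, so pipelines are reproducible without clobbering a
  session's RNG.

## Problem sizes

The test suite and the acceptance script run on scaled campaigns —
typically 4–10 spectra per session (224–560 spectra per run), 200-point
oracle segments, 2000-replicate null calibrations, 200-replicate power
runs — sizes at which every check completes in seconds while the
statistics remain decisive. The generator defaults themselves are
full-scale.

## Known limitations

* The concave-rubberband reconstruction matches the *purpose* of the
  proprietary instrument-software method (removing concave fluorescence
  backgrounds) with a published-literature hull-plus-bending iteration;
  coefficient-level agreement with any specific vendor implementation is
  not claimed.
* Band extraction does no peak fitting or deconvolution; heavily
  overlapped bands share window maxima.
* No cosmic-ray removal or wavenumber re-calibration; spectra are assumed
  on a common axis.
* The KW χ² approximation is asymptotic; at very small per-day counts
  (< 5) exact methods would be preferable.
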