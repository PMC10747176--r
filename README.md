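# ramalgae

Chemometric analysis of Raman spectra time series for monitoring microalgal
bioprocesses under nitrogen starvation.

## The problem

In-line Raman spectroscopy can follow a microalgal culture (e.g.
*Parachlorella kessleri*) through its whole production cycle without
sampling: pigment bands (chlorophyll ~988 cm⁻¹, carotenoids ~1157 and
~1524 cm⁻¹) dominate during growth, and once nitrogen runs out the cells
stop dividing, degrade pigments and accumulate storage lipids, which shows
up as rising triacylglycerol (~1750 cm⁻¹) and unsaturation (~1660,
~3008 cm⁻¹) bands. Turning raw in-line spectra into that physiological
story requires a chain of standard chemometric steps, each with enough
free choices that end-to-end testing matters. `ramalgae` implements the
full chain as composable, tested functions:

1. **Pre-processing** — crop to the fingerprint (350–1800 cm⁻¹) and C–H
   stretch (2800–3050 cm⁻¹) windows; remove the chlorophyll-fluorescence
   background with an iterative *concave (bent) rubberband*: per iteration
   the lower convex hull of the spectrum is computed in a frame bent by
   b(x) = tan(θ)·A·(x−x₀)(x₁−x)/((x₁−x₀)/2)² (θ = 64°, A the working
   intensity range, 10 iterations), and the baseline interpolates the
   spectrum between the hull touch points; smooth twice with a 25-point
   quadratic Savitzky–Golay filter; normalize each spectrum by the
   standard normal variate, SNV(y) = (y − ȳ)/s_y.
2. **Quality control** — all-pairs Pearson correlation map, per-day
   repeatability (mean ± sd of the m(m−1)/2 within-day pairwise
   correlations), similarity to a reference day, daily median spectra.
3. **Band kinetics** — per-spectrum band intensities (windowed maximum,
   ±8 cm⁻¹) at the assigned wavenumbers (479, 865, 988, 1157, 1444, 1524,
   1660, 1750, 2850, 2885, 2940, 2970, 3008 cm⁻¹), ratiometric indices
   (unsaturation index I₁₆₆₀/I₁₄₄₄, carotenoid ratio I₁₁₅₇/I₁₅₂₄), and
   per-day mean ± sd series.
4. **Chemometrics** — mean-centered PCA (explained fractions σᵢ²/Σσ²) and
   a tie-corrected Kruskal–Wallis test of culture-day groups on PC1,
   H = [12/(N(N+1)) Σ Rⱼ²/nⱼ − 3(N+1)] / (1 − Σ(t³−t)/(N³−N)),
   with Dunn-type adjacent-day post-hoc comparisons under Bonferroni
   control.
5. **Quantification** — the spectrophotometric pigment equations
   (chl a = (V_e/V_b)(−8.0962·A₆₅₂ + 16.5169·A₆₆₅), chl b =
   (V_e/V_b)(27.4405·A₆₅₂ − 12.1688·A₆₆₅), carotenoids = (V_e/V_b)·4·A₄₈₀,
   all after subtracting the 750 nm turbidity), gravimetric total lipids
   (mg extract / L sample), and dilution-corrected optical density.

No culture spectra of this kind are publicly deposited, so the package
ships a seeded generator (`simulate_spectra()`) that emulates such
campaigns: Gaussian/Lorentzian bands with two-phase amplitude kinetics,
a quadratic-plus-exponential fluorescence background, multiplicative
per-spectrum scatter jitter and additive white noise, on either the bench
schedule (50 spectra/day × 36 days) or the pilot schedule (4 sessions/day
× 50 spectra × 14 days). All statistical claims in the test suite are
made against this generator's known ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → preprocess → QC → kinetics → PCA/KW → quantification). Running
it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_qc.R
Rscript analysis/04_band_kinetics.R
Rscript analysis/05_chemometrics.R
Rscript analysis/06_quantification.R
```

prints, among other things:

```
pilot: 560 spectra (14 days x 4 sessions x 10 replicates), 1401 axis points
pilot: 1401 -> 852 axis points in 2 segments; mean 97% of raw intensity removed as background
overall pairwise correlation: 0.839 +/- 0.178 over 560 spectra
similarity to day 0 falls from 0.987 (day 1) to 0.632 (final day)
unsaturation index 1660/1444: 0.70 (day 0) -> 2.04 (final day), +190%
explained variance: PC1 91.8%, PC2 1.4%, PC3 0.9%
Kruskal-Wallis on PC1 by day: H = 503.6, df = 13, p = 2.48e-99
adjacent days with significantly different median ranks: 2-3, 8-9
total lipids rise from 27.77 to 48.85 mg/L across the starvation phase
```

Reading: spectral quality is high within days (repeatability ≥ 0.975) but
the culture drifts steadily from its day-0 state; the unsaturation index
nearly triples as storage lipids accumulate; PC1 cleanly separates the
pigment-rich phase (through the day-8 nitrogen switch) from the
lipid-rich phase, and the adjacent-day rank comparison flags exactly the
programmed transition (8→9) plus the end of the early pigment ramp-up
(2→3). All result tables land under `results/`.

The same pipeline is available as one call:

```r
library(ramalgae)
cfg <- default_config("pilot", seed = 1)
res <- run_pipeline(run_config(sim = cfg, seed = 1, out_dir = "results/run"))
```

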