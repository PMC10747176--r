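Package: ramalgae
Title: Chemometric Monitoring of Microalgal Cultures from Raman Spectra Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated Raman monitoring of microalgal bioprocesses
    under nitrogen starvation. Implements the full chemometric chain used for
    in-line culture surveillance: spectral-range cropping, iterative concave
    (bent) rubberband baseline correction, double Savitzky-Golay smoothing and
    standard normal variate (SNV) normalization; correlation-based spectral
    quality control (all-pairs correlation maps, per-day repeatability,
    similarity to a reference day, daily median spectra); band-intensity
    kinetics at assigned vibrational bands with ratiometric indices
    (unsaturation index 1660/1444, carotenoid ratio 1157/1524); principal
    component analysis with a tie-corrected Kruskal-Wallis test of culture-day
    groups and Dunn-type post-hoc rank comparisons; and spectrophotometric
    pigment and gravimetric lipid quantification arithmetic. Because no
    culture spectra are publicly deposited, a seeded synthetic generator
    reproduces the statistical structure of such time series (assigned bands
    with two-phase amplitude kinetics, fluorescence background, multiplicative
    scatter jitter, additive noise) for testing and method development.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
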