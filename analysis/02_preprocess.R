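#!/usr/bin/env Rscript
# Pre-process both campaigns: crop to the fingerprint and C-H windows,
# remove the fluorescence background with the concave rubberband
# (64 degrees, 10 iterations), smooth twice with a 25-point quadratic
# Savitzky-Golay filter, and SNV-normalize each spectrum.

library(ramalgae)

params <- preprocess_params()
for (scen in c("pilot", "lab")) {
  set <- read_spectra(file.path("results/data", paste0(scen, "_raw.tsv")))
  prep <- preprocess(set, params)
  write_spectra(prep, file.path("results/data", paste0(scen, "_preprocessed.tsv")))
  lg <- attr(prep, "log")
  cat(sprintf("%-5s: %d -> %d axis points in %d segments; mean %.0f%% of raw intensity removed as background\n",
              scen, lg$points_in, lg$points_retained, lg$segments,
              100 * lg$mean_baseline_fraction))
}
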