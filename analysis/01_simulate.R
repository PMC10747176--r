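#!/usr/bin/env Rscript
# Generate the synthetic culture runs analysed by the rest of the workflow.
#
# Two campaigns are emulated: a bench photobioreactor sampled once daily
# (36 days) and an automated pilot loop sampled four times daily (14 days).
# Replicate counts are scaled to 10 per session so the whole workflow runs
# in seconds; the schedules, band kinetics, background and noise model are
# the full-scale ones.

library(ramalgae)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (scen in c("pilot", "lab")) {
  cfg <- default_config(scen, seed = 1)
  cfg$spectra_per_session <- 10L
  set <- simulate_spectra(cfg)
  write_spectra(set, file.path(out, paste0(scen, "_raw.tsv")))
  write_config(cfg, file.path(out, paste0(scen, "_config.yaml")))
  cat(sprintf("%-5s: %d spectra (%d days x %d sessions x %d replicates), %d axis points\n",
              scen, n_spectra(set), cfg$days, cfg$sessions_per_day,
              cfg$spectra_per_session, length(set$axis)))
}
cat("wrote raw spectra and configs under", out, "\n")
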