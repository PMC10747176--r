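#!/usr/bin/env Rscript
# Spectral quality control of the pilot campaign: all-pairs correlation
# structure, per-day repeatability, similarity to the first day, and daily
# median spectra around the nitrogen switch.

library(ramalgae)

prep <- read_spectra("results/data/pilot_preprocessed.tsv")
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

cm <- correlation_map(prep)
cat(sprintf("overall pairwise correlation: %.3f +/- %.3f over %d spectra\n",
            cm$overall["mean"], cm$overall["sd"], n_spectra(prep)))

rep_tab <- repeatability(prep)
write.table(rep_tab, "results/qc/repeatability.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("within-day repeatability ranges %.3f (day %d) to %.3f (day %d)\n",
            min(rep_tab$mean), rep_tab$day[which.min(rep_tab$mean)],
            max(rep_tab$mean), rep_tab$day[which.max(rep_tab$mean)]))

sim_tab <- similarity_to_reference(prep, 0)
write.table(sim_tab, "results/qc/similarity_day0.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("similarity to day 0 falls from %.3f (day 1) to %.3f (final day):\n",
            sim_tab$mean[sim_tab$day == 1], sim_tab$mean[nrow(sim_tab)]))
cat("  the culture drifts away from its inoculation state as nitrogen runs out\n")

# daily medians bracketing the nitrogen switch (day 8)
med_days <- c(0, 4, 8, 11, 13)
meds <- do.call(rbind, lapply(med_days, function(d)
  median_spectrum(prep, d)$intensities))
med_tab <- data.frame(wavenumber = prep$axis, t(meds))
names(med_tab)[-1] <- paste0("day", med_days)
write.table(format(med_tab, digits = 8), "results/qc/median_spectra.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("median spectra for days", paste(med_days, collapse = ", "),
    "written to results/qc/median_spectra.tsv\n")
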