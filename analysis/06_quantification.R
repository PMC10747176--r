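#!/usr/bin/env Rscript
# Reference wet-lab arithmetic on a worked absorbance/gravimetry panel:
# pigment concentrations with turbidity correction, total lipid
# concentration, dilution-corrected optical density. The panel is synthetic
# (values in the typical range of nitrogen-starved green microalgae).

library(ramalgae)

dir.create("results/quantification", recursive = TRUE, showWarnings = FALSE)

panel <- data.frame(
  day = c(0, 3, 7, 10, 12),
  A480 = c(0.35, 0.62, 0.60, 0.30, 0.22),
  A652 = c(0.28, 0.55, 0.52, 0.22, 0.15),
  A665 = c(0.40, 0.78, 0.74, 0.31, 0.21),
  A750 = c(0.02, 0.03, 0.03, 0.02, 0.02),
  V_biomass = c(1.5, 1.0, 1.0, 1.5, 1.5),
  od650_measured = c(0.21, 0.45, 0.62, 0.55, 0.52),
  dilution = c(1, 2, 5, 5, 5),
  lipid_mg = c(NA, NA, 27.77, 40.1, 48.85),
  lipid_volume_L = c(NA, NA, 1, 1, 1))

pig <- pigment_concentrations(panel$A480, panel$A652, panel$A665, panel$A750,
                              panel$V_biomass)
od <- corrected_od(panel$od650_measured, panel$dilution)
lipid <- rep(NA_real_, nrow(panel))
ok <- !is.na(panel$lipid_mg)
lipid[ok] <- total_lipid_concentration(panel$lipid_mg[ok],
                                       panel$lipid_volume_L[ok])

out <- data.frame(day = panel$day, pig[, 1:3], od650 = od$od,
                  od_flag = od$out_of_range, lipid_mg_per_L = lipid)
write.table(format(out, digits = 6), "results/quantification/panel.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("chlorophyll a peaks at %.2f ug/mL (day %d) then falls to %.2f ug/mL\n",
            max(pig$chl_a), panel$day[which.max(pig$chl_a)],
            pig$chl_a[nrow(panel)]))
cat(sprintf("total lipids rise from %.2f to %.2f mg/L across the starvation phase\n",
            min(lipid, na.rm = TRUE), max(lipid, na.rm = TRUE)))
cat("results written to results/quantification/panel.tsv\n")
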