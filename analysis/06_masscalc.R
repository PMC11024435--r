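#!/usr/bin/env Rscript
# HRMS mass calculus on the isolated acylphloroglucinols: theoretical
# [M+H]+ m/z, ppm errors against the observed values, and constrained
# formula assignment from the observed m/z alone.

suppressMessages(library(extractprio))

# observed [M+H]+ m/z and assigned neutral formulas of the isolated
# compounds (the printed ion formulas carry one H more than the neutral)
compounds <- data.frame(
  compound = c("1", "2", "4", "6", "7", "10"),
  observed_mz = c(509.2894, 479.2793, 509.2894, 509.2894, 509.2893,
                  479.2791),
  neutral = c("C31H40O6", "C30H38O5", "C31H40O6", "C31H40O6", "C31H40O6",
              "C30H38O5"),
  stringsAsFactors = FALSE)

compounds$theoretical_mz <- vapply(compounds$neutral, adduct_mz, numeric(1))
compounds$error_ppm <- round_half_away(
  ppm_error(compounds$observed_mz, compounds$theoretical_mz), 2)
print(compounds, row.names = FALSE, digits = 10)

dir.create("results", showWarnings = FALSE)
write.table(compounds, "results/hrms_errors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# formula assignment from scratch over CHO bounds at 5 ppm
bounds <- list(C = c(0, 35), H = c(0, 60), O = c(0, 8))
for (i in c(2, 1)) {
  hits <- assign_formula(compounds$observed_mz[i], "[M+H]+", 5, bounds)
  cat(sprintf("compound %s (m/z %.4f): top assignment %s (%+.2f ppm)\n",
              compounds$compound[i], compounds$observed_mz[i],
              hits$ion_formula[1], hits$error_ppm[1]))
}
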