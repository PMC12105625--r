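#!/usr/bin/env Rscript
# pH dependence of the oxidation potential for a representative acidic
# nucleobase couple (xanthine-like: pKa(0)r 7.5, radical cation pKa 3)
# under the three pH-aware models, on a 0-14 grid.

suppressPackageStartupMessages(library(redoxpH))
dir.create("results", showWarnings = FALSE)

ab <- acid_base_spec(pKa_oxidized = 3, pKa_reduced = 7.5)
# neutral-pathway M1 of 1.89 V vs SHE, deprotonated 0.92 V (xanthine-like)
cp <- redox_couple(1.89 + 4.281, 0.92 + 4.281, ab)

curves <- rbind(speciation_curve(cp, "M2"),
                speciation_curve(cp, "M3"),
                speciation_curve(cp, "M4"))
write_results(curves, "results/speciation_curves.csv", "csv")

at7 <- curves[curves$pH == 7, ]
cat("E at pH 7 (V vs SHE):\n")
for (i in seq_len(nrow(at7)))
  cat(sprintf("  %s: %.2f\n", at7$model[i], round_display(at7$E_volts[i])))
cat("All three curves fall with pH (the radical cation is the stronger\n")
cat("acid); M3/M4 plateau below the cation pKa and above the neutral pKa.\n")
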