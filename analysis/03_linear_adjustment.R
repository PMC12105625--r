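#!/usr/bin/env Rscript
# Linear adjustment of the absolute pH 7 M4 potentials: scale each series
# by the benchmark regression slope (0.60) and anchor the intercept on the
# experimental cytosine (1.44 V) or uracil (1.34 V) value. Writes the
# adjusted potentials and reports the resulting substituent trend for the
# epigenetic cytosine marks.

suppressPackageStartupMessages(library(redoxpH))
dir.create("results", showWarnings = FALSE)

t5 <- load_fixture("table5")
ura <- grepl("U$", t5$compound) | t5$compound %in% c("T", "1mT")
cyt <- !ura

adjust_series <- function(rows, anchor, anchor_E) {
  out <- lapply(c("M4_SMD_DFT", "M4_SMD_DFT_H2O", "M4_SMD_CBS",
                  "M4_SMD_CBS_H2O"), function(col) {
    raw <- stats::setNames(t5[[col]][rows], t5$compound[rows])
    adj <- linear_adjust(raw, adjustment_rule(0.60, anchor, anchor_E))
    data.frame(compound = names(raw), column = col, raw = unname(raw),
               E_volts = unname(adj$adjusted),
               intercept = adj$derived_intercept)
  })
  do.call(rbind, out)
}

adjusted <- rbind(adjust_series(cyt, "C", 1.44),
                  adjust_series(ura, "U", 1.34))
write_results(adjusted, "results/adjusted_potentials.csv", "csv")

best <- adjusted[adjusted$column == "M4_SMD_CBS_H2O" &
                   adjusted$compound %in% c("C", "5mC", "5hmC", "5fC",
                                            "5dhmC", "5caC", "d_5caC"), ]
best <- best[order(best$E_volts), ]
cat("Adjusted pH 7 potentials, cytosine marks (SMD/CBS + H2O, V vs SHE):\n")
for (i in seq_len(nrow(best)))
  cat(sprintf("  %-7s %.2f\n", best$compound[i], round_display(best$E_volts[i])))
cat("Trend:", paste(best$compound, collapse = " < "), "\n")
cat("(5mC and 5caC tie at the printed 0.01 V precision; unrounded values\n")
cat("place 5caC marginally below 5mC.)\n")
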