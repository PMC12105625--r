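#!/usr/bin/env Rscript
# Benchmark calibration: how well do the computed gas-phase ionization
# energies and acetonitrile oxidation potentials track experiment?
# Regresses each method column of the benchmark table on the experimental
# values (the censored uracil acetonitrile entry resolved at its bound)
# and writes the fit statistics.

suppressPackageStartupMessages(library(redoxpH))
dir.create("results", showWarnings = FALSE)

t2 <- load_fixture("table2")

fit_column <- function(col, exp_col, cens_col = NULL) {
  ok <- !is.na(t2[[col]]) & !is.na(t2[[exp_col]])
  cens <- if (!is.null(cens_col)) t2[[cens_col]][ok] else "exact"
  pairs <- paired_observations(t2$compound[ok], t2[[col]][ok],
                               t2[[exp_col]][ok], censoring = cens)
  fit <- fit_linear(resolve_bounds(pairs, "at_bound"))
  data.frame(column = col, n = fit$n, slope = fit$slope,
             intercept = fit$intercept, r_squared = fit$r_squared,
             mse = fit$mse, mue = fit$mue, rmse = fit$rmse)
}

fits <- rbind(
  fit_column("AIE_DFT", "AIE_exp"),
  fit_column("AIE_CBS", "AIE_exp"),
  fit_column("Eac_SMD_DFT", "Eac_exp", "Eac_exp_censoring"),
  fit_column("Eac_SMD_CBS", "Eac_exp", "Eac_exp_censoring"))

write_results(fits, "results/benchmark_fits.csv", "csv")

cat("Benchmark regressions (theory vs experiment):\n")
for (i in seq_len(nrow(fits)))
  cat(sprintf("  %-12s n=%d  slope %.2f  intercept %+.2f  R2 %.2f  MUE %.2f  RMSE %.2f\n",
              fits$column[i], fits$n[i], fits$slope[i], fits$intercept[i],
              fits$r_squared[i], fits$mue[i], fits$rmse[i]))
cat("Gas phase and acetonitrile track experiment closely (R2 ~ 0.9-1.0,\n")
cat("slopes ~ 1 for the CBS columns); this is the regime where the raw\n")
cat("thermodynamic-cycle potential (M1) is adequate.\n")
cat("Note: the benchmark table's experimental AIE for uracil (8.68 eV)\n")
cat("disagrees with the 9.32 eV of the reference table and drags the\n")
cat("recomputed gas-phase correlation below the printed one; dropping U:\n")
noU <- t2[t2$compound != "U", ]
ok <- !is.na(noU$AIE_CBS)
f <- fit_linear(paired_observations(noU$compound[ok], noU$AIE_CBS[ok],
                                    noU$AIE_exp[ok]))
cat(sprintf("  AIE_CBS without U: n=%d  slope %.2f  R2 %.2f\n",
            f$n, f$slope, f$r_squared))
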