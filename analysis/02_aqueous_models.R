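#!/usr/bin/env Rscript
# Aqueous-solution model comparison. First recomposes the mole-fraction
# averaged (M2) rows of the aqueous M1/M2 table from their printed pathway
# components and the Henderson-Hasselbalch fractions; then regresses the
# M1 and the Nernst-corrected M3/M4 columns on experiment to show why the
# prototropic treatment is needed in water.

suppressPackageStartupMessages(library(redoxpH))
dir.create("results", showWarnings = FALSE)

t3 <- load_fixture("table3")
t4 <- load_fixture("table4")

# --- M2 recomposition for the acidic purines -------------------------------
cols <- c("E_SMD_DFT", "E_SMD_DFT_H2O", "E_SMD_CBS", "E_SMD_CBS_H2O")
cases <- list(list(sp = "X", d = "d_X", pH = 7, pKa = 7.5),
              list(sp = "hX", d = "d_hX", pH = 7, pKa = 8.9),
              list(sp = "hX", d = "d_hX", pH = 9, pKa = 8.9))
recomp <- do.call(rbind, lapply(cases, function(cs) {
  neu <- t3[t3$compound == cs$sp & t3$row_type == "M1_neutral", ]
  dep <- t3[t3$compound == cs$d & t3$row_type == "M1_deprotonated", ]
  bold <- t3[t3$compound == cs$sp & t3$row_type == "M2" & t3$pH == cs$pH, ]
  do.call(rbind, lapply(cols, function(col) {
    cp <- redox_couple(neu[[col]] + 4.281, dep[[col]] + 4.281,
                       acid_base_spec(pKa_reduced = cs$pKa))
    e2 <- m2_potential(cp, cs$pH)$E
    data.frame(compound = cs$sp, pH = cs$pH, column = col,
               E_volts = e2, E_printed = bold[[col]],
               x_RH = mole_fractions(cs$pH, cs$pKa)$x_RH)
  }))
}))
write_results(recomp, "results/m2_recomposition.csv", "csv")
cat("M2 recomposition: max |recomputed - printed| =",
    sprintf("%.3f V", max(abs(recomp$E_volts - recomp$E_printed))),
    "(printed inputs are rounded to 0.01 V)\n")

# --- aqueous regressions ----------------------------------------------------
aq_fit <- function(df, col) {
  ok <- !is.na(df[[col]]) & !is.na(df$E_exp)
  fit <- fit_linear(paired_observations(df$compound[ok], df[[col]][ok],
                                        df$E_exp[ok]))
  data.frame(column = col, n = fit$n, slope = fit$slope,
             intercept = fit$intercept, r_squared = fit$r_squared,
             mse = fit$mse, mue = fit$mue, rmse = fit$rmse)
}
m1_rows <- t3[t3$row_type %in% c("M1", "M2") & !is.na(t3$E_exp) & t3$pH == 7, ]
fits <- rbind(
  aq_fit(m1_rows, "E_SMD_CBS_H2O"),
  aq_fit(t4, "M3_SMD_CBS_H2O"),
  aq_fit(t4, "M4_SMD_CBS_H2O"))
fits$model <- c("M1/M2", "M3", "M4")
write_results(fits, "results/aqueous_model_fits.csv", "csv")

cat("\nAqueous regressions (SMD/CBS + one explicit water):\n")
for (i in seq_len(nrow(fits)))
  cat(sprintf("  %-5s R2 %.2f  slope %.2f  intercept %+.2f\n",
              fits$model[i], fits$r_squared[i], fits$slope[i],
              fits$intercept[i]))
cat("M1 shows essentially no aqueous correlation; the Nernst prototropic\n")
cat("corrections restore it, with M4 (both pathways) the strongest.\n")
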