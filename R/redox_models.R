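# The four oxidation-potential models (M1-M4), acidity conversions,
# Henderson-Hasselbalch mole fractions, pathway selection and E-vs-pH
# speciation curves.
#
# Naming convention for acidity constants, after the four-corner scheme
# RH / R- (reduced) and RH+. / R. (oxidized):
#   Ka_oxidized = Ka of the radical cation RH+. (first deprotonation of the
#                 oxidized form), pKa(+1)o in the usual notation;
#   Ka_reduced  = Ka of the neutral molecule RH, pKa(0)r;
#   pKa_anion   = optional second deprotonation of the reduced form, pKa(-1)r.

#' Acid-base specification of a redox couple
#'
#' Acidity constants may be given as pKa values or as literal Ka values
#' (which admit the `Ka = 0` "non-acidic" sentinel that has no finite pKa).
#' A literal Ka takes precedence over the corresponding pKa.
#'
#' @param pKa_oxidized pKa of the oxidized radical cation (RH+.).
#' @param pKa_reduced pKa of the neutral reduced molecule (RH).
#' @param pKa_anion Optional pKa of the reduced anion (R-).
#' @param Ka_oxidized,Ka_reduced Literal acidity constants; `0` flags a
#'   non-acidic species.
#' @return An `acid_base_spec` list with elements `Ka_oxidized`,
#'   `Ka_reduced`, `pKa_oxidized`, `pKa_reduced`, `pKa_anion`.
#' @export
acid_base_spec <- function(pKa_oxidized = NULL, pKa_reduced = NULL,
                           pKa_anion = NULL,
                           Ka_oxidized = NULL, Ka_reduced = NULL) {
  resolve <- function(Ka, pKa, what) {
    if (!is.null(Ka)) {
      stopifnot(is.finite(Ka), Ka >= 0)
      return(Ka)
    }
    if (!is.null(pKa) && is.finite(pKa)) return(10^(-pKa))
    0 # non-acidic sentinel
  }
  ka_o <- resolve(Ka_oxidized, pKa_oxidized)
  ka_r <- resolve(Ka_reduced, pKa_reduced)
  structure(
    list(Ka_oxidized = ka_o, Ka_reduced = ka_r,
         pKa_oxidized = if (ka_o > 0) -log10(ka_o) else NA_real_,
         pKa_reduced = if (ka_r > 0) -log10(ka_r) else NA_real_,
         pKa_anion = if (is.null(pKa_anion)) NA_real_ else pKa_anion),
    class = "acid_base_spec"
  )
}

#' Deprotonation free energy from a pKa value
#'
#' dG_a = RT ln(10) pKa, i.e. about 5.71 kJ/mol per pKa unit at 298.15 K.
#'
#' @param pKa Acidity constant exponent (finite; may be negative).
#' @param temperature Temperature in K.
#' @return Free energy of deprotonation, kJ/mol.
#' @export
pka_to_deltaG <- function(pKa, temperature = 298.15) {
  stopifnot(all(is.finite(pKa)), temperature > 0)
  rt_kjmol(temperature) * log(10) * pKa
}

#' Henderson-Hasselbalch mole fractions of an acid/base pair
#'
#' x_RH = 1 / (1 + 10^(pH - pKa)), x_R- = 1 - x_RH.
#'
#' @param pH Solution pH.
#' @param pKa Acidity constant exponent of the dissociating species.
#' @return A list with `x_RH` and `x_Rminus` (each in \[0, 1\], summing to 1).
#' @export
mole_fractions <- function(pH, pKa) {
  stopifnot(is.finite(pH), is.finite(pKa))
  x_RH <- 1 / (1 + 10^(pH - pKa))
  list(x_RH = x_RH, x_Rminus = 1 - x_RH)
}

potential_result <- function(model, E, pH = NA_real_, reference = "SHE",
                             pathway = "neutral") {
  structure(list(model = model, E = E, pH = pH, reference = reference,
                 pathway = pathway),
            class = "potential_result")
}

#' @export
print.potential_result <- function(x, ...) {
  cat(sprintf("E(%s%s) = %.4f V vs %s [%s pathway]\n", x$model,
              if (is.na(x$pH)) "" else sprintf(", pH %.2g", x$pH),
              x$E, x$reference, x$pathway))
  invisible(x)
}

#' @export
as.data.frame.potential_result <- function(x, ...) {
  data.frame(model = x$model, E_volts = x$E, pH = x$pH,
             reference = x$reference, pathway = x$pathway,
             stringsAsFactors = FALSE)
}

#' A one-electron redox couple with its two oxidation pathways
#'
#' Holds the solution-phase ionization free energies of the neutral
#' (RH -> RH+.) and, when available, deprotonated (R- -> R.) pathways,
#' in eV per electron, together with the acid-base specification.
#' Removing an electron from the electron-rich anion is always easier, so
#' `dG_IE_deprotonated <= dG_IE_neutral` is enforced when both are present
#' (equality being the degenerate-acidity limit).
#'
#' @param dG_IE_neutral Solution ionization free energy of RH -> RH+., eV.
#' @param dG_IE_deprotonated Optional analogue for R- -> R., eV.
#' @param acid_base An [acid_base_spec()].
#' @param reference Reference electrode label.
#' @return A `redox_couple` list.
#' @export
redox_couple <- function(dG_IE_neutral, dG_IE_deprotonated = NULL,
                         acid_base = acid_base_spec(),
                         reference = c("SHE", "SCE")) {
  reference <- match.arg(reference)
  stopifnot(is.finite(dG_IE_neutral), inherits(acid_base, "acid_base_spec"))
  if (!is.null(dG_IE_deprotonated)) {
    stopifnot(is.finite(dG_IE_deprotonated))
    # equality is the degenerate-acidity limit and is admitted
    if (dG_IE_deprotonated > dG_IE_neutral)
      stop("the deprotonated pathway must lie below the neutral one ",
           "(dG_IE(-1)r <= dG_IE(0)r); got ", dG_IE_deprotonated, " > ",
           dG_IE_neutral, " eV")
  }
  structure(list(dG_IE_neutral = dG_IE_neutral,
                 dG_IE_deprotonated = dG_IE_deprotonated,
                 acid_base = acid_base, reference = reference),
            class = "redox_couple")
}

#' Model M1: standard oxidation potential from the thermodynamic cycle
#'
#' E = dG_IE_sol / n - ref, with dG_IE_sol expressed in eV per electron so
#' the division by the Faraday constant is implicit in the unit.
#'
#' @param dG_IE_sol Solution-phase ionization free energy, eV.
#' @param constants A [redox_constants()] (supplies n and the reference).
#' @param pathway Pathway label recorded on the result.
#' @return A `potential_result` (model "M1", no pH dependence).
#' @export
m1_potential <- function(dG_IE_sol, constants = redox_constants(),
                         pathway = "neutral") {
  stopifnot(is.finite(dG_IE_sol), inherits(constants, "redox_constants"))
  potential_result("M1",
                   dG_IE_sol / constants$n_electrons - constants$ref_potential,
                   pH = NA_real_, reference = constants$reference,
                   pathway = pathway)
}

#' Model M2: mole-fraction-weighted potential over both pathways
#'
#' The neutral and deprotonated oxidation pathways are mixed with the
#' Henderson-Hasselbalch mole fractions of RH and R- at the given pH:
#' E = x_RH E_M1(neutral) + x_R- E_M1(deprotonated). Because the map from
#' free energy to potential is affine, this equals the mole-fraction
#' weighted free energy divided by nF minus the reference.
#'
#' @param couple A [redox_couple()]; its `acid_base` must carry the
#'   reduced-species acidity (pKa(0)r).
#' @param pH Solution pH.
#' @param temperature Temperature in K.
#' @return A `potential_result` (model "M2", mixed pathway).
#' @export
m2_potential <- function(couple, pH, temperature = 298.15) {
  stopifnot(inherits(couple, "redox_couple"), is.finite(pH))
  ab <- couple$acid_base
  consts <- redox_constants(temperature, reference = couple$reference)
  if (ab$Ka_reduced == 0) {
    x <- list(x_RH = 1, x_Rminus = 0) # non-acidic: only the neutral pathway
  } else {
    x <- mole_fractions(pH, ab$pKa_reduced)
  }
  if (x$x_Rminus > 1e-12 && is.null(couple$dG_IE_deprotonated))
    stop("x_R- = ", signif(x$x_Rminus, 3), " at pH ", pH,
         " but the couple has no deprotonated-pathway free energy")
  E_n <- m1_potential(couple$dG_IE_neutral, consts)$E
  E_d <- if (is.null(couple$dG_IE_deprotonated)) 0
         else m1_potential(couple$dG_IE_deprotonated, consts)$E
  potential_result("M2", x$x_RH * E_n + x$x_Rminus * E_d, pH = pH,
                   reference = couple$reference, pathway = "mixed")
}

#' Nernst prototropic correction term of model M3
#'
#' (RT/F) ln\[(10^-pH + Ka(0)r) / (10^-pH + Ka(+1)o)\]. Negative whenever
#' the radical cation is more acidic than the neutral molecule
#' (Ka(+1)o > Ka(0)r), which holds for all systems treated here.
#'
#' @param Ka_reduced,Ka_oxidized Literal acidity constants (>= 0).
#' @param pH Solution pH.
#' @param temperature Temperature in K.
#' @return Correction in volts.
#' @export
prototropic_correction <- function(Ka_reduced, Ka_oxidized, pH,
                                   temperature = 298.15) {
  stopifnot(is.finite(pH), Ka_reduced >= 0, Ka_oxidized >= 0)
  h <- 10^(-pH)
  num <- h + Ka_reduced
  den <- h + Ka_oxidized
  if (num <= 0 || den <= 0)
    stop("prototropic correction undefined: 10^-pH + Ka must be positive ",
         "in both numerator and denominator")
  nernst_rt_over_f(temperature) * log(num / den)
}

#' Model M3: Nernst correction of one oxidation pathway
#'
#' E = E° + (RT/F) ln\[(10^-pH + Ka(0)r)/(10^-pH + Ka(+1)o)\], treating
#' only the RH <-> RH+. pathway and excluding the R- <-> R. contribution.
#'
#' @param E_standard Standard potential E° of the treated pathway, V.
#' @param acid_base An [acid_base_spec()].
#' @param pH Solution pH.
#' @param temperature Temperature in K.
#' @param reference Reference electrode label recorded on the result.
#' @param pathway Pathway label recorded on the result.
#' @return A `potential_result` (model "M3").
#' @export
m3_potential <- function(E_standard, acid_base, pH, temperature = 298.15,
                         reference = "SHE", pathway = "neutral") {
  stopifnot(is.finite(E_standard), inherits(acid_base, "acid_base_spec"))
  corr <- prototropic_correction(acid_base$Ka_reduced, acid_base$Ka_oxidized,
                                 pH, temperature)
  potential_result("M3", E_standard + corr, pH = pH, reference = reference,
                   pathway = pathway)
}

#' Acid-base neutralization term of model M4
#'
#' (RT/F) ln(Ka(+1)o / Ka(0)r): the reverse (sign-flipped) free energy of
#' the endergonic neutralization RH+. + R- <-> R. + RH. Positive whenever
#' the radical cation is the stronger acid.
#'
#' @param Ka_oxidized,Ka_reduced Literal acidity constants, both > 0.
#' @param temperature Temperature in K.
#' @return Term value in volts.
#' @export
neutralization_term <- function(Ka_oxidized, Ka_reduced,
                                temperature = 298.15) {
  if (!(Ka_oxidized > 0 && Ka_reduced > 0))
    stop("neutralization_term needs strictly positive Ka for both states")
  nernst_rt_over_f(temperature) * log(Ka_oxidized / Ka_reduced)
}

#' Model M4: Nernst treatment of both oxidation pathways
#'
#' E = E° + (RT/F) ln(Ka(+1)o/Ka(0)r)
#'        + 2 (RT/F) ln\[(10^-pH + Ka(0)r)/(10^-pH + Ka(+1)o)\].
#' The first term is the neutralization term (always > 0 V when the radical
#' cation is the stronger acid); the pH/Ka term of M3 enters twice because
#' the added activities (R. and R-) are governed by the same two acidity
#' constants.
#'
#' @inheritParams m3_potential
#' @return A `potential_result` (model "M4").
#' @export
m4_potential <- function(E_standard, acid_base, pH, temperature = 298.15,
                         reference = "SHE", pathway = "neutral") {
  stopifnot(is.finite(E_standard), inherits(acid_base, "acid_base_spec"))
  if (acid_base$Ka_reduced <= 0)
    stop("M4 requires Ka(0)r > 0; for a non-acidic reduced species use M3 ",
         "or the deprotonated pathway directly")
  term1 <- neutralization_term(acid_base$Ka_oxidized, acid_base$Ka_reduced,
                               temperature)
  term2 <- 2 * prototropic_correction(acid_base$Ka_reduced,
                                      acid_base$Ka_oxidized, pH, temperature)
  potential_result("M4", E_standard + term1 + term2, pH = pH,
                   reference = reference, pathway = pathway)
}

#' Choose the oxidation pathway for an acidic species
#'
#' For strongly acidic molecules the deprotonated form dominates at the
#' working pH and the deprotonated-pathway standard potential is the
#' appropriate E°. Returns `"deprotonated"` iff x_R- strictly exceeds
#' `threshold` at the given pH (ties go to neutral).
#'
#' @param couple A [redox_couple()] (or an [acid_base_spec()]).
#' @param pH Solution pH.
#' @param threshold Mole-fraction threshold (default 0.5).
#' @return `"neutral"` or `"deprotonated"`.
#' @export
select_pathway <- function(couple, pH, threshold = 0.5) {
  ab <- if (inherits(couple, "redox_couple")) couple$acid_base else couple
  stopifnot(inherits(ab, "acid_base_spec"))
  if (ab$Ka_reduced == 0) return("neutral")
  x <- mole_fractions(pH, ab$pKa_reduced)
  if (x$x_Rminus > threshold) "deprotonated" else "neutral"
}

#' E-versus-pH speciation curve for a redox couple
#'
#' Evaluates M2, M3 or M4 over a pH grid. For M3/M4 the standard potential
#' defaults to the M1 value of the neutral pathway; pass `E_standard` to
#' override (e.g. with the deprotonated-pathway M1 value for acidic
#' species).
#'
#' @param couple A [redox_couple()].
#' @param model `"M2"`, `"M3"` or `"M4"`.
#' @param pH_grid Ascending, non-empty pH grid (default 0-14 by 0.1).
#' @param E_standard Optional E° for M3/M4, V.
#' @param temperature Temperature in K.
#' @return A data.frame with columns `pH`, `E_volts`, `model`, `reference`.
#' @export
speciation_curve <- function(couple, model = c("M3", "M4", "M2"),
                             pH_grid = seq(0, 14, by = 0.1),
                             E_standard = NULL, temperature = 298.15) {
  model <- match.arg(model)
  stopifnot(inherits(couple, "redox_couple"), length(pH_grid) >= 1)
  if (is.unsorted(pH_grid, strictly = TRUE))
    stop("pH_grid must be strictly ascending")
  consts <- redox_constants(temperature, reference = couple$reference)
  if (is.null(E_standard)) E_standard <- m1_potential(couple$dG_IE_neutral, consts)$E
  E <- vapply(pH_grid, function(p) {
    switch(model,
           M2 = m2_potential(couple, p, temperature)$E,
           M3 = m3_potential(E_standard, couple$acid_base, p, temperature,
                             reference = couple$reference)$E,
           M4 = m4_potential(E_standard, couple$acid_base, p, temperature,
                             reference = couple$reference)$E)
  }, numeric(1))
  data.frame(pH = pH_grid, E_volts = E, model = model,
             reference = couple$reference, stringsAsFactors = FALSE)
}
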