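# Solution-phase free-energy assembly and thermodynamic-cycle quantities.

#' Per-conformer energy components entering the solution-phase free energy
#'
#' @param E_tot Single-point electronic energy, hartree.
#' @param ZPE Zero-point vibrational energy, hartree (non-negative).
#' @param dG_thermal Thermal correction 0 K -> 298 K, hartree.
#' @param dG_solv Solvation free energy, kJ/mol.
#' @param apply_standard_state Add the 1 atm -> 1 mol/l correction?
#' @return A `thermo_components` list.
#' @export
thermo_components <- function(E_tot, ZPE = 0, dG_thermal = 0, dG_solv = 0,
                              apply_standard_state = TRUE) {
  vals <- c(E_tot, ZPE, dG_thermal, dG_solv)
  stopifnot(is.numeric(vals), all(is.finite(vals)), ZPE >= 0,
            is.logical(apply_standard_state))
  structure(list(E_tot = E_tot, ZPE = ZPE, dG_thermal = dG_thermal,
                 dG_solv = dG_solv,
                 apply_standard_state = isTRUE(apply_standard_state)),
            class = "thermo_components")
}

#' Assemble the solution-phase free energy G_sol
#'
#' G_sol = E_tot + ZPE + dG_thermal (hartree terms, converted) +
#' the 1 atm -> 1 mol/l standard-state correction (if requested) + dG_solv,
#' reported in kJ/mol.
#'
#' @param components A [thermo_components()] object.
#' @param constants A [redox_constants()] object supplying the
#'   standard-state correction.
#' @return G_sol in kJ/mol.
#' @export
assemble_gsol <- function(components, constants = redox_constants()) {
  stopifnot(inherits(components, "thermo_components"),
            inherits(constants, "redox_constants"))
  gas <- convert_energy(components$E_tot + components$ZPE + components$dG_thermal,
                        "hartree", "kJ/mol")
  ss <- if (components$apply_standard_state) constants$dG_1atm_to_1M else 0
  gas + ss + components$dG_solv
}

#' Solvation free energy from same-geometry phase energies
#'
#' dG_solv = G(solution phase, solution-optimised geometry) -
#' G(gas phase single point, same geometry).
#'
#' @param G_solution,G_gas Free energies of the two phases.
#' @param unit_solution,unit_gas Unit tags; must match.
#' @return The difference in the shared unit.
#' @export
solvation_free_energy <- function(G_solution, G_gas,
                                  unit_solution = "hartree",
                                  unit_gas = unit_solution) {
  match_unit(unit_solution)
  match_unit(unit_gas)
  if (!identical(unit_solution, unit_gas)) {
    stop("unit mismatch: solution-phase energy in '", unit_solution,
         "' but gas-phase energy in '", unit_gas, "'")
  }
  stopifnot(is.finite(G_solution), is.finite(G_gas))
  G_solution - G_gas
}

#' Adiabatic ionization energy from optimised gas-phase energies
#'
#' AIE = E(cation radical, optimised) - E(neutral, optimised), in eV.
#' Both energies must be gas-phase totals; solution-phase differences go
#' through [oxidation_free_energy_solution()].
#'
#' @param G_neutral,G_cation Total energies of the optimised neutral and
#'   cation-radical geometries.
#' @param unit Unit tag of both inputs.
#' @param phase Must be `"gas"`.
#' @return AIE in eV (positive for a bound electron).
#' @export
adiabatic_ionization_energy <- function(G_neutral, G_cation,
                                        unit = "hartree", phase = "gas") {
  if (!identical(phase, "gas")) {
    stop("adiabatic_ionization_energy is a gas-phase quantity; ",
         "use oxidation_free_energy_solution() for the solution phase")
  }
  stopifnot(is.finite(G_neutral), is.finite(G_cation))
  convert_energy(G_cation - G_neutral, unit, "eV")
}

#' Solution-phase one-electron oxidation free energy
#'
#' Closes the thermodynamic cycle: the gas-phase ionization free energy plus
#' the difference of the cation and neutral solvation free energies.
#'
#' @param dG_IE_gas Gas-phase ionization free energy.
#' @param dG_solv_cation,dG_solv_neutral Solvation free energies of the
#'   radical cation and the neutral; all three in the same unit.
#' @return dG_IE_gas + dG_solv_cation - dG_solv_neutral.
#' @export
oxidation_free_energy_solution <- function(dG_IE_gas, dG_solv_cation,
                                           dG_solv_neutral) {
  stopifnot(is.finite(dG_IE_gas), is.finite(dG_solv_cation),
            is.finite(dG_solv_neutral))
  dG_IE_gas + dG_solv_cation - dG_solv_neutral
}

#' Two-point complete-basis-set extrapolation
#'
#' Inverse-power two-point extrapolation on total energies for the
#' cc-pVTZ/cc-pVQZ cardinal pair:
#' E_CBS = (Y^p E_Y - X^p E_X) / (Y^p - X^p), default exponent p = 3.
#'
#' @param E_TZ,E_QZ Total energies at the smaller (X) and larger (Y) basis.
#' @param X,Y Cardinal numbers, Y > X >= 2.
#' @param exponent Extrapolation exponent (default 3).
#' @return Extrapolated basis-set-limit energy, same unit as the inputs.
#' @export
cbs_extrapolate <- function(E_TZ, E_QZ, X = 3, Y = 4, exponent = 3) {
  stopifnot(is.finite(E_TZ), is.finite(E_QZ), X >= 2, exponent > 0)
  if (Y <= X) stop("cardinal numbers must satisfy Y > X (got X = ", X, ", Y = ", Y, ")")
  (Y^exponent * E_QZ - X^exponent * E_TZ) / (Y^exponent - X^exponent)
}
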