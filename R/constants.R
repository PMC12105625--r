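# Single source of truth for physical and conversion constants.
# 1 hartree = 27.2114 eV = 2625.50 kJ/mol; derived eV <-> kJ/mol factor
# (96.4853 kJ/mol per eV) follows from the two, so one electron-volt of
# free energy per particle is one volt of potential per electron.
.hartree_in <- c("hartree" = 1, "eV" = 27.2114, "kJ/mol" = 2625.50)

.REF_POTENTIALS <- c(SHE = 4.281, SCE = 4.429) # absolute electrode potentials, V

#' Convert an energy value between hartree, eV and kJ/mol
#'
#' @param value Numeric energy value(s); must be finite.
#' @param from,to Unit tags, one of `"hartree"`, `"eV"`, `"kJ/mol"`.
#' @return The converted value, same length as `value`.
#' @examples
#' convert_energy(1, "hartree", "eV") # 27.2114
#' @export
convert_energy <- function(value, from, to) {
  from <- match_unit(from)
  to <- match_unit(to)
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * .hartree_in[[to]] / .hartree_in[[from]]
}

match_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1 || !unit %in% names(.hartree_in)) {
    stop("unknown energy unit '", paste(unit, collapse = ","),
         "'; supported units are: ", paste(names(.hartree_in), collapse = ", "))
  }
  unit
}

#' Physical constants and run conditions for potential calculations
#'
#' Bundles the gas constant, Faraday constant, temperature, electron count,
#' reference-electrode potential and the 1 atm -> 1 mol/l standard-state
#' correction used when assembling solution-phase free energies.
#'
#' @param temperature Temperature in K (default 298.15).
#' @param n_electrons Electrons transferred per redox event (default 1).
#' @param reference Reference electrode, `"SHE"` (aqueous, absolute 4.281 V)
#'   or `"SCE"` (acetonitrile, absolute 4.429 V).
#' @param standard_state `"literal"` stores the conventional +7.91 kJ/mol
#'   correction; `"recomputed"` derives it as RT*ln(24.46) (~7.93 kJ/mol at
#'   298.15 K) from the molar volume of an ideal gas at 1 atm.
#' @return An object of class `redox_constants`: a list with elements
#'   `R` (J/mol/K), `T` (K), `F` (C/mol), `n_electrons`, `reference`,
#'   `ref_potential` (V) and `dG_1atm_to_1M` (kJ/mol).
#' @export
redox_constants <- function(temperature = 298.15, n_electrons = 1L,
                            reference = c("SHE", "SCE"),
                            standard_state = c("literal", "recomputed")) {
  reference <- match.arg(reference)
  standard_state <- match.arg(standard_state)
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0,
            n_electrons >= 1)
  R <- 8.31446
  ss <- if (standard_state == "literal") 7.91 else R * temperature * log(24.46) / 1000
  structure(
    list(R = R, T = temperature, F = 96485.3,
         n_electrons = as.integer(n_electrons),
         reference = reference,
         ref_potential = unname(.REF_POTENTIALS[reference]),
         dG_1atm_to_1M = ss),
    class = "redox_constants"
  )
}

#' @export
print.redox_constants <- function(x, ...) {
  cat("redox_constants: T =", x$T, "K,", x$n_electrons, "e-, ref", x$reference,
      sprintf("(%.3f V), 1atm->1M %+.2f kJ/mol\n", x$ref_potential, x$dG_1atm_to_1M))
  invisible(x)
}

# RT/F in volts (the Nernst prefactor for n = 1)
nernst_rt_over_f <- function(temperature = 298.15) {
  8.31446 * temperature / 96485.3
}

# Gas constant in kJ/mol/K, for Boltzmann factors on kJ/mol energies
rt_kjmol <- function(temperature = 298.15) {
  8.31446 * temperature / 1000
}
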