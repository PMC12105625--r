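# Synthetic redox systems with known ground truth: conformer/tautomer
# ensembles with controlled energy spreads and four-corner couples whose
# standard potential and pKa ladder are fixed by construction, so every
# pipeline stage can be validated offline against closed forms.

#' Specification of a synthetic redox system
#'
#' @param seed Integer seed; all randomness in the generators derives from
#'   it, and outputs are bit-identical under a fixed seed.
#' @param true_E_standard Ground-truth standard oxidation potential of the
#'   neutral pathway, V vs SHE.
#' @param pKa_ladder Acidity ladder `c(pKa(+1)o, pKa(0)r[, pKa(-1)r])`:
#'   radical cation first, then the neutral reduced molecule, optionally the
#'   reduced anion. The cation may not be a weaker acid than the neutral
#'   (pKa(+1)o <= pKa(0)r). A single entry is read as pKa(0)r alone, giving
#'   a neutral-pathway-only couple.
#' @param n_tautomers,n_conformers_per_tautomer Ensemble sizes (>= 1).
#' @param conformer_spread Upper bound of the conformer energy offsets
#'   above the global minimum, kJ/mol.
#' @param solvation_shift_cation Solvation free energy assigned to charged
#'   species when the system is written out as a species-energies table,
#'   kJ/mol (charged solutes are strongly stabilised, hence large negative).
#' @param noise_sd Gaussian noise on the corner free energies, kJ/mol.
#' @return A `synthetic_system_spec` list.
#' @export
synthetic_system_spec <- function(seed = 1L, true_E_standard = 1.45,
                                  pKa_ladder = c(4.2, 9.5),
                                  n_tautomers = 2L,
                                  n_conformers_per_tautomer = 3L,
                                  conformer_spread = 5,
                                  solvation_shift_cation = -250,
                                  noise_sd = 0) {
  stopifnot(length(pKa_ladder) >= 1, all(is.finite(pKa_ladder)),
            n_tautomers >= 1, n_conformers_per_tautomer >= 1,
            conformer_spread >= 0, noise_sd >= 0,
            is.finite(true_E_standard))
  if (length(pKa_ladder) >= 2 && pKa_ladder[1] > pKa_ladder[2])
    stop("inconsistent pKa ladder: the oxidized radical cation must not be ",
         "a weaker acid than the neutral molecule (pKa(+1)o <= pKa(0)r)")
  structure(list(seed = as.integer(seed), true_E_standard = true_E_standard,
                 pKa_ladder = pKa_ladder,
                 n_tautomers = as.integer(n_tautomers),
                 n_conformers_per_tautomer = as.integer(n_conformers_per_tautomer),
                 conformer_spread = conformer_spread,
                 solvation_shift_cation = solvation_shift_cation,
                 noise_sd = noise_sd),
            class = "synthetic_system_spec")
}

# Conformer energy offsets above the state's minimum. The same spectrum is
# reused for every redox/protonation corner, so Boltzmann averaging shifts
# all four corner free energies equally and the constructed couple survives
# ensemble averaging exactly (at zero noise).
synthetic_offsets <- function(spec) {
  n <- spec$n_tautomers * spec$n_conformers_per_tautomer
  if (n == 1 || spec$conformer_spread == 0) return(rep(0, n))
  withr::with_seed(spec$seed, {
    off <- pmin(stats::rexp(n - 1, rate = 3 / spec$conformer_spread),
                spec$conformer_spread)
    c(0, sort(off))
  })
}

# Gaussian perturbations of the three corner free-energy differences
# (ionization, neutral deprotonation, cation deprotonation), kJ/mol.
synthetic_noise <- function(spec) {
  if (spec$noise_sd == 0) return(c(0, 0, 0))
  withr::with_seed(spec$seed + 1L, stats::rnorm(3, 0, spec$noise_sd))
}

# Ensemble minimum free energies of the four corners, kJ/mol. An arbitrary
# (physically meaningless) baseline anchors the reduced neutral corner;
# only differences matter downstream. Deprotonated corners absorb the
# proton free energy into the bookkeeping.
synthetic_corners <- function(spec) {
  ev_kj <- convert_energy(1, "eV", "kJ/mol")
  eps <- synthetic_noise(spec)
  dG_IE0 <- (spec$true_E_standard + 4.281) * ev_kj + eps[1]
  G_red0 <- -1312750 # ~ -500 hartree baseline
  corners <- list(reduced.neutral = G_red0, oxidized.neutral = G_red0 + dG_IE0)
  if (length(spec$pKa_ladder) >= 2) {
    dGa_r <- pka_to_deltaG(spec$pKa_ladder[2]) + eps[2]
    dGa_o <- pka_to_deltaG(spec$pKa_ladder[1]) + eps[3]
    corners$reduced.deprotonated <- G_red0 + dGa_r
    # four-corner closure: dG_IE(-1)r = dG_IE(0)r + dG_a(+1)o - dG_a(0)r
    corners$oxidized.deprotonated <- corners$reduced.deprotonated +
      dG_IE0 + dGa_o - dGa_r
  }
  corners
}

#' Generate one synthetic species ensemble
#'
#' Conformer free energies are the corner minimum plus bounded
#' exponential-like offsets (identical spectra across corners; see
#' [generate_redox_couple()]). Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_system_spec()].
#' @param redox_state `"reduced"` or `"oxidized"`.
#' @param protonation `"neutral"` or `"deprotonated"`.
#' @return A [species_ensemble()].
#' @export
generate_ensemble <- function(spec, redox_state = c("reduced", "oxidized"),
                              protonation = c("neutral", "deprotonated")) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  redox_state <- match.arg(redox_state)
  protonation <- match.arg(protonation)
  key <- paste(redox_state, protonation, sep = ".")
  corners <- synthetic_corners(spec)
  if (is.null(corners[[key]]))
    stop("the pKa ladder has a single entry; no deprotonated corner exists")
  off <- synthetic_offsets(spec)
  ids <- expand.grid(conf = seq_len(spec$n_conformers_per_tautomer),
                     taut = seq_len(spec$n_tautomers))
  charge <- switch(key, reduced.neutral = 0L, oxidized.neutral = 1L,
                   reduced.deprotonated = -1L, oxidized.deprotonated = 0L)
  recs <- conformer_records(
    species_id = paste0("syn", spec$seed),
    tautomer_id = paste0("t", ids$taut),
    conformer_id = paste0("t", ids$taut, "c", ids$conf),
    G_sol = corners[[key]] + off)
  species_ensemble(recs, charge = charge, redox_state = redox_state)
}

#' Generate a synthetic redox couple with its ground truth
#'
#' Builds the (up to) four corner ensembles and assembles the couple from
#' their Boltzmann-averaged free energies. At zero noise the neutral
#' pathway's M1 potential equals `true_E_standard` exactly, and the
#' deprotonated pathway follows from the four-corner thermodynamic
#' closure, which automatically places it below the neutral one.
#'
#' @param spec A [synthetic_system_spec()].
#' @return A list with `couple` (a [redox_couple()]), `ensembles` (named
#'   list of [species_ensemble()]s) and `truth` (the generating values).
#' @export
generate_redox_couple <- function(spec) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  has_deprot <- length(spec$pKa_ladder) >= 2
  states <- list(c("reduced", "neutral"), c("oxidized", "neutral"))
  if (has_deprot) states <- c(states, list(c("reduced", "deprotonated"),
                                           c("oxidized", "deprotonated")))
  ens <- lapply(states, function(s) generate_ensemble(spec, s[1], s[2]))
  names(ens) <- vapply(states, paste, "", collapse = ".")
  ev_kj <- convert_energy(1, "eV", "kJ/mol")
  g <- function(k) ens[[k]]$G_sol_ensemble
  dG_n <- (g("oxidized.neutral") - g("reduced.neutral")) / ev_kj
  dG_d <- if (has_deprot)
    (g("oxidized.deprotonated") - g("reduced.deprotonated")) / ev_kj else NULL
  ab <- if (has_deprot) {
    acid_base_spec(pKa_oxidized = spec$pKa_ladder[1],
                   pKa_reduced = spec$pKa_ladder[2],
                   pKa_anion = if (length(spec$pKa_ladder) >= 3)
                     spec$pKa_ladder[3] else NULL)
  } else {
    acid_base_spec(pKa_reduced = spec$pKa_ladder[1])
  }
  list(couple = redox_couple(dG_n, dG_d, acid_base = ab, reference = "SHE"),
       ensembles = ens,
       truth = list(E_standard = spec$true_E_standard,
                    pKa_ladder = spec$pKa_ladder,
                    dG_IE_neutral = dG_n, dG_IE_deprotonated = dG_d))
}

#' Write a synthetic system as a species-energies table
#'
#' Decomposes each conformer's total G_sol into the species-energies file
#' schema (single-point energy, ZPE, thermal correction, solvation term)
#' such that reading the file back and reassembling G_sol reproduces the
#' generated ensembles exactly. Charged corners carry the spec's cation
#' solvation shift; neutral corners a modest -30 kJ/mol.
#'
#' @param spec A [synthetic_system_spec()].
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_synthetic_energies <- function(spec, path) {
  sys <- generate_redox_couple(spec)
  ss <- redox_constants()$dG_1atm_to_1M
  rows <- lapply(names(sys$ensembles), function(key) {
    e <- sys$ensembles[[key]]
    dG_solv <- if (e$charge == 0L) -30 else spec$solvation_shift_cation
    zpe <- 0.08
    dth <- -0.01
    e_tot <- convert_energy(e$records$G_sol - ss - dG_solv, "kJ/mol", "hartree") -
      zpe - dth
    data.frame(species_id = e$species_id,
               state = e$redox_state,
               protonation = if (grepl("deprotonated", key)) -1L else 0L,
               tautomer_id = e$records$tautomer_id,
               conformer_id = e$records$conformer_id,
               E_tot_au = e_tot, ZPE_au = zpe, dG_thermal_au = dth,
               dG_solv_kjmol = dG_solv, basis_tag = "none",
               explicit_waters = 0L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
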