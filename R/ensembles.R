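# Conformer/tautomer bookkeeping: Boltzmann weighting, ensemble free
# energies, duplicate detection and the explicit-water contribution filter.

#' Build a conformer record table
#'
#' One row per conformer/tautomer structure of a species in a fixed charge
#' and oxidation state. `descriptor` holds optional geometry descriptors
#' (per-record numeric vectors of atom-to-centroid distances, in Angstrom).
#'
#' @param species_id,tautomer_id,conformer_id Label vectors (recycled).
#' @param G_sol Solution-phase free energies, kJ/mol.
#' @param descriptor Optional list of numeric vectors, one per record.
#' @return A data.frame of class `conformer_records`.
#' @export
conformer_records <- function(species_id, tautomer_id, conformer_id, G_sol,
                              descriptor = NULL) {
  stopifnot(is.numeric(G_sol), all(is.finite(G_sol)))
  df <- data.frame(species_id = as.character(species_id),
                   tautomer_id = as.character(tautomer_id),
                   conformer_id = as.character(conformer_id),
                   G_sol = G_sol,
                   stringsAsFactors = FALSE)
  if (!is.null(descriptor)) {
    stopifnot(is.list(descriptor), length(descriptor) == nrow(df))
    bad <- vapply(descriptor, function(d)
      !is.null(d) && (!is.numeric(d) || any(d < 0)), logical(1))
    if (any(bad)) stop("geometry descriptors must be non-negative numeric vectors")
    df$descriptor <- I(descriptor)
  }
  class(df) <- c("conformer_records", "data.frame")
  df
}

record_gsol <- function(records) {
  if (is.data.frame(records)) records$G_sol else as.numeric(records)
}

#' Boltzmann weights of an energy set
#'
#' Weights proportional to exp(-(G_i - min G)/RT); the common shift makes
#' the evaluation overflow-safe and leaves the weights unchanged.
#'
#' @param G Free energies in kJ/mol (non-empty).
#' @param temperature Temperature in K.
#' @return Weights summing to 1.
#' @export
boltzmann_weights <- function(G, temperature = 298.15) {
  G <- record_gsol(G)
  if (length(G) == 0) stop("cannot weight an empty energy set")
  stopifnot(all(is.finite(G)), temperature > 0)
  w <- exp(-(G - min(G)) / rt_kjmol(temperature))
  w / sum(w)
}

#' Ensemble free energy of a conformer set
#'
#' `weighted_mean` returns the Boltzmann-weighted mean sum(w_i G_i);
#' `partition_sum` returns the partition-function free energy
#' -RT log sum(exp(-G_i/RT)), which lies at or below the lowest member.
#' Both reduce to the single record's G for a one-member ensemble.
#'
#' @param records A `conformer_records` table or numeric vector of G_sol
#'   values, kJ/mol.
#' @param temperature Temperature in K.
#' @param mode Averaging convention.
#' @return Ensemble free energy, kJ/mol.
#' @export
ensemble_gsol <- function(records, temperature = 298.15,
                          mode = c("weighted_mean", "partition_sum")) {
  mode <- match.arg(mode)
  G <- record_gsol(records)
  if (length(G) == 0) stop("cannot average an empty ensemble")
  RT <- rt_kjmol(temperature)
  if (mode == "weighted_mean") {
    sum(boltzmann_weights(G, temperature) * G)
  } else {
    min(G) - RT * log(sum(exp(-(G - min(G)) / RT)))
  }
}

#' Remove duplicate conformers by energy and geometry criteria
#'
#' Two records are duplicates when their free energies agree within
#' `energy_threshold` (expressed in hartree, the convention for this
#' criterion) and their sorted atom-to-centroid distance lists agree
#' element-wise within `geometry_tolerance`. Records without descriptors
#' are compared on energy alone. Each duplicate group keeps its lowest-G
#' member (ties broken by lexicographic conformer_id); the operation is
#' idempotent.
#'
#' @param records A `conformer_records` table.
#' @param energy_threshold Energy criterion in hartree (default 1e-7 au).
#' @param geometry_tolerance Element-wise descriptor tolerance, Angstrom.
#' @return The unique records, in ascending G_sol order.
#' @export
deduplicate <- function(records, energy_threshold = 1e-7,
                        geometry_tolerance = 0.01) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$species_id)) > 1)
    stop("deduplicate expects records of a single species")
  thr_kj <- convert_energy(energy_threshold, "hartree", "kJ/mol")
  ord <- order(records$G_sol, records$conformer_id)
  records <- records[ord, , drop = FALSE]
  has_desc <- "descriptor" %in% names(records)

  same_geometry <- function(i, j) {
    if (!has_desc) return(TRUE)
    di <- records$descriptor[[i]]
    dj <- records$descriptor[[j]]
    # one (or both) descriptor missing: the energy criterion governs
    if (is.null(di) || is.null(dj)) return(TRUE)
    if (length(di) != length(dj)) return(FALSE)
    all(abs(sort(di) - sort(dj)) <= geometry_tolerance)
  }

  keep <- integer(0)
  for (i in seq_len(nrow(records))) {
    dup <- FALSE
    for (k in keep) {
      if (abs(records$G_sol[i] - records$G_sol[k]) <= thr_kj && same_geometry(i, k)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper bound on the number of tautomers
#'
#' For an asymmetric molecule with `n` lone pairs and `k` acidic protons
#' the number of distinct proton arrangements is the binomial coefficient
#' n! / ((n-k)! k!).
#'
#' @param n_lone_pairs,k_acidic_protons Non-negative counts, k <= n.
#' @return The count as a numeric scalar.
#' @export
tautomer_count <- function(n_lone_pairs, k_acidic_protons) {
  stopifnot(n_lone_pairs >= 0, k_acidic_protons >= 0)
  if (k_acidic_protons > n_lone_pairs)
    stop("k_acidic_protons (", k_acidic_protons, ") exceeds n_lone_pairs (",
         n_lone_pairs, ")")
  choose(n_lone_pairs, k_acidic_protons)
}

#' Retain conformers contributing more than a weight threshold
#'
#' Keeps the records whose Boltzmann weight exceeds `threshold`
#' (default 2%). The lowest-G record is always retained, so the result is
#' never empty even when every individual weight is at or below threshold.
#'
#' @param records A `conformer_records` table or numeric G_sol vector.
#' @param threshold Weight threshold as a fraction.
#' @param temperature Temperature in K.
#' @return The retained subset (same type as the input).
#' @export
contribution_filter <- function(records, threshold = 0.02,
                                temperature = 298.15) {
  G <- record_gsol(records)
  w <- boltzmann_weights(G, temperature)
  keep <- w > threshold
  if (!any(keep)) keep[which.min(G)] <- TRUE
  if (is.data.frame(records)) {
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    records[keep]
  }
}

#' Group conformer records into a species ensemble
#'
#' @param records A `conformer_records` table (single species).
#' @param charge Integer charge of the species.
#' @param redox_state `"reduced"` or `"oxidized"`.
#' @param temperature Temperature in K.
#' @param mode Averaging convention passed to [ensemble_gsol()].
#' @return A `species_ensemble` list with the records, the Boltzmann
#'   weights and the ensemble free energy `G_sol_ensemble` (kJ/mol).
#' @export
species_ensemble <- function(records, charge = 0L,
                             redox_state = c("reduced", "oxidized"),
                             temperature = 298.15,
                             mode = c("weighted_mean", "partition_sum")) {
  redox_state <- match.arg(redox_state)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  sid <- unique(records$species_id)
  if (length(sid) != 1) stop("an ensemble holds exactly one species")
  w <- boltzmann_weights(records$G_sol, temperature)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  structure(
    list(species_id = sid, charge = as.integer(charge),
         redox_state = redox_state, records = records, weights = w,
         temperature = temperature, mode = mode,
         G_sol_ensemble = ensemble_gsol(records, temperature, mode)),
    class = "species_ensemble"
  )
}

#' @export
print.species_ensemble <- function(x, ...) {
  cat(sprintf("species_ensemble %s (q = %+d, %s): %d conformer(s), G_sol = %.3f kJ/mol\n",
              x$species_id, x$charge, x$redox_state, nrow(x$records),
              x$G_sol_ensemble))
  invisible(x)
}
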