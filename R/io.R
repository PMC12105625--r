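# Species-energies file schema, pipeline orchestration and result output.

.species_energy_columns <- c("species_id", "state", "protonation",
                             "tautomer_id", "conformer_id", "E_tot_au",
                             "ZPE_au", "dG_thermal_au", "dG_solv_kjmol",
                             "basis_tag", "explicit_waters")

#' Round half away from zero (display convention for printed tables)
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, matching the tables).
#' @return Rounded values.
#' @export
round_display <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a species-energies table into species ensembles
#'
#' The CSV schema carries one row per conformer per basis: species_id,
#' state (reduced/oxidized), protonation (integer charge of the reduced
#' parent: 0 neutral, -1 deprotonated), tautomer_id, conformer_id,
#' E_tot_au, ZPE_au, dG_thermal_au, dG_solv_kjmol, basis_tag (TZ/QZ/none),
#' explicit_waters. When both TZ and QZ rows exist for a conformer its
#' single-point energy is CBS-extrapolated; each conformer's G_sol is then
#' assembled with the standard-state correction and the rows grouped into
#' one ensemble per (species_id, state, protonation).
#'
#' @param path CSV file path (or a data.frame already in the schema).
#' @param constants A [redox_constants()].
#' @param temperature,mode Passed to [species_ensemble()].
#' @return A named list of [species_ensemble()] objects, names
#'   `"<species_id>.<state>.<protonation>"`.
#' @export
read_species_energies <- function(path, constants = redox_constants(),
                                  temperature = 298.15,
                                  mode = "weighted_mean") {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.species_energy_columns, names(df))
  if (length(missing_cols) > 0)
    stop("species-energies table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("species-energies table is empty")
  if (!all(df$state %in% c("reduced", "oxidized")))
    stop("state must be 'reduced' or 'oxidized'")
  if (!all(df$basis_tag %in% c("TZ", "QZ", "none")))
    stop("basis_tag must be 'TZ', 'QZ' or 'none'")
  key_full <- do.call(paste, c(df[c("species_id", "state", "protonation",
                                    "tautomer_id", "conformer_id",
                                    "basis_tag")], sep = "|"))
  if (anyDuplicated(key_full)) {
    dup_rows <- which(key_full %in% key_full[duplicated(key_full)])
    stop("duplicate (species, state, protonation, tautomer, conformer, basis) ",
         "key in rows: ", paste(dup_rows, collapse = ", "))
  }

  # collapse basis pairs: CBS-extrapolate the single-point energy when a
  # conformer has both TZ and QZ rows
  key_conf <- do.call(paste, c(df[c("species_id", "state", "protonation",
                                    "tautomer_id", "conformer_id")],
                               sep = "|"))
  conf_rows <- split(seq_len(nrow(df)), key_conf)
  collapsed <- lapply(conf_rows, function(rows) {
    sub <- df[rows, , drop = FALSE]
    if (all(c("TZ", "QZ") %in% sub$basis_tag)) {
      tz <- sub[sub$basis_tag == "TZ", , drop = FALSE][1, ]
      qz <- sub[sub$basis_tag == "QZ", , drop = FALSE][1, ]
      out <- qz
      out$E_tot_au <- cbs_extrapolate(tz$E_tot_au, qz$E_tot_au)
      out$basis_tag <- "CBS"
      out
    } else {
      sub[1, , drop = FALSE]
    }
  })
  flat <- do.call(rbind, collapsed)
  flat$G_sol <- vapply(seq_len(nrow(flat)), function(i) {
    assemble_gsol(thermo_components(flat$E_tot_au[i], flat$ZPE_au[i],
                                    flat$dG_thermal_au[i],
                                    flat$dG_solv_kjmol[i]),
                  constants)
  }, numeric(1))

  key_ens <- do.call(paste, c(flat[c("species_id", "state", "protonation")],
                              sep = "."))
  groups <- split(flat, key_ens)
  out <- lapply(groups, function(g) {
    recs <- conformer_records(g$species_id, g$tautomer_id, g$conformer_id,
                              g$G_sol)
    charge <- g$protonation[1] + if (g$state[1] == "oxidized") 1L else 0L
    species_ensemble(recs, charge = charge, redox_state = g$state[1],
                     temperature = temperature, mode = mode)
  })
  out
}

#' Pipeline run configuration
#'
#' @param model Requested potential model, `"M1"` ... `"M4"`.
#' @param pH Working pH (ignored by M1).
#' @param reference Reference electrode label.
#' @param temperature Temperature in K.
#' @param averaging_mode Ensemble averaging convention.
#' @param adjustment Optional [adjustment_rule()] applied to the results.
#' @param force_neutral_pathway If TRUE, M3/M4 always use the neutral
#'   pathway's E° instead of the one chosen by [select_pathway()].
#' @return A `run_config` list.
#' @export
run_config <- function(model = c("M4", "M3", "M2", "M1"), pH = 7,
                       reference = c("SHE", "SCE"), temperature = 298.15,
                       averaging_mode = c("weighted_mean", "partition_sum"),
                       adjustment = NULL, force_neutral_pathway = FALSE) {
  model <- match.arg(model)
  reference <- match.arg(reference)
  averaging_mode <- match.arg(averaging_mode)
  stopifnot(is.finite(pH), temperature > 0)
  if (!is.null(adjustment)) stopifnot(inherits(adjustment, "adjustment_rule"))
  structure(list(model = model, pH = pH, reference = reference,
                 temperature = temperature, averaging_mode = averaging_mode,
                 adjustment = adjustment,
                 force_neutral_pathway = isTRUE(force_neutral_pathway)),
            class = "run_config")
}

#' Run the oxidation-potential pipeline over a species-energies table
#'
#' For each species the ensemble free energies give the solution ionization
#' free energies of the neutral and (when present) deprotonated pathways;
#' the configured model then yields the potential. Species without acidity
#' data fall back to M1 with a logged notice (the caffeine case: no acidic
#' protons, so the prototropic machinery does not apply). Species with
#' missing required states produce an error note and the run continues.
#'
#' @param config A [run_config()].
#' @param energies Path to a species-energies CSV, a data.frame in that
#'   schema, or a named ensemble list from [read_species_energies()].
#' @param pka_table Optional data.frame with columns `species_id`,
#'   `pKa_oxidized` (radical cation) and `pKa_reduced` (neutral molecule).
#' @return A data.frame with one row per species: pathway free energies,
#'   the model used, `E_volts`, a 2-decimal `E_display` column and `note`.
#'   Per-species intermediates (ensemble G_sol values, mole fractions,
#'   correction terms) are attached as the `"details"` attribute.
#' @export
run_pipeline <- function(config, energies, pka_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  consts <- redox_constants(config$temperature, reference = config$reference)
  ens <- if (is.list(energies) && !is.data.frame(energies) &&
             all(vapply(energies, inherits, logical(1), "species_ensemble")))
    energies
  else if (is.data.frame(energies) && nrow(energies) == 0)
    list()
  else read_species_energies(energies, consts, config$temperature,
                             config$averaging_mode)
  if (length(ens) == 0) {
    return(data.frame(species_id = character(0), model_requested = character(0),
                      model_used = character(0), pathway = character(0),
                      pH = numeric(0), reference = character(0),
                      E_volts = numeric(0), E_display = numeric(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  species <- unique(vapply(ens, function(e) e$species_id, ""))
  ev_kj <- convert_energy(1, "eV", "kJ/mol")
  details <- list()

  rows <- lapply(species, function(sp) {
    get_g <- function(state, prot) {
      e <- ens[[paste(sp, state, prot, sep = ".")]]
      if (is.null(e)) NULL else e$G_sol_ensemble
    }
    g_r0 <- get_g("reduced", 0L)
    g_o0 <- get_g("oxidized", 0L)
    base <- data.frame(species_id = sp, model_requested = config$model,
                       model_used = NA_character_, pathway = NA_character_,
                       pH = config$pH, reference = config$reference,
                       dG_IE_neutral_eV = NA_real_,
                       dG_IE_deprotonated_eV = NA_real_,
                       E_volts = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (is.null(g_r0) || is.null(g_o0)) {
      base$note <- "missing reduced/oxidized neutral state; species skipped"
      return(base)
    }
    dG_n <- (g_o0 - g_r0) / ev_kj
    g_rm <- get_g("reduced", -1L)
    g_om <- get_g("oxidized", -1L)
    dG_d <- if (!is.null(g_rm) && !is.null(g_om)) (g_om - g_rm) / ev_kj else NULL

    pka_row <- if (!is.null(pka_table)) pka_table[pka_table$species_id == sp, ]
               else NULL
    has_pka <- !is.null(pka_row) && nrow(pka_row) == 1 &&
      is.finite(pka_row$pKa_reduced)
    ab <- if (has_pka) {
      acid_base_spec(
        pKa_oxidized = if (is.finite(pka_row$pKa_oxidized))
          pka_row$pKa_oxidized else NULL,
        pKa_reduced = pka_row$pKa_reduced)
    } else {
      acid_base_spec() # non-acidic
    }

    model <- config$model
    note <- ""
    if (model != "M1" && !has_pka) {
      note <- "no acidity data; fell back to M1 (non-acidic species)"
      model <- "M1"
    }
    if (model == "M4" && ab$Ka_oxidized == 0) {
      note <- "no radical-cation pKa; fell back to M3"
      model <- "M3"
    }

    couple <- tryCatch(
      redox_couple(dG_n, dG_d, acid_base = ab, reference = config$reference),
      error = function(e) e)
    if (inherits(couple, "error")) {
      base$note <- conditionMessage(couple)
      base$dG_IE_neutral_eV <- dG_n
      return(base)
    }

    pathway <- if (config$force_neutral_pathway || !has_pka) "neutral"
               else select_pathway(couple, config$pH)
    if (pathway == "deprotonated" && is.null(dG_d)) {
      pathway <- "neutral"
      note <- paste0(note, if (nzchar(note)) "; ",
                     "deprotonated pathway favoured but absent; used neutral")
    }
    E_std <- m1_potential(
      if (pathway == "deprotonated") dG_d else dG_n, consts, pathway)$E

    res <- tryCatch(switch(model,
      M1 = m1_potential(if (pathway == "deprotonated") dG_d else dG_n,
                        consts, pathway),
      M2 = m2_potential(couple, config$pH, config$temperature),
      M3 = m3_potential(E_std, ab, config$pH, config$temperature,
                        reference = config$reference, pathway = pathway),
      M4 = m4_potential(E_std, ab, config$pH, config$temperature,
                        reference = config$reference, pathway = pathway)),
      error = function(e) e)
    if (inherits(res, "error")) {
      base$note <- conditionMessage(res)
      base$dG_IE_neutral_eV <- dG_n
      return(base)
    }

    details[[sp]] <<- list(
      G_sol = list(reduced_neutral = g_r0, oxidized_neutral = g_o0,
                   reduced_deprotonated = g_rm, oxidized_deprotonated = g_om),
      mole_fractions = if (has_pka) mole_fractions(config$pH, ab$pKa_reduced)
                       else list(x_RH = 1, x_Rminus = 0),
      E_standard = E_std)

    base$model_used <- res$model
    base$pathway <- res$pathway
    base$dG_IE_neutral_eV <- dG_n
    base$dG_IE_deprotonated_eV <- if (is.null(dG_d)) NA_real_ else dG_d
    base$E_volts <- res$E
    base$note <- note
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$adjustment)) {
    ok <- !is.na(out$E_volts)
    raw <- stats::setNames(out$E_volts[ok], out$species_id[ok])
    adj <- linear_adjust(raw, config$adjustment)
    out$E_adjusted <- NA_real_
    out$E_adjusted[ok] <- unname(adj$adjusted)
  }
  out$E_display <- round_display(out$E_volts)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Write pipeline results to CSV or JSON
#'
#' Columns are written in a stable order; numeric values keep full
#' precision and `E_display` carries the 2-decimal display rounding
#' (half away from zero, matching printed tables).
#'
#' @param results A results data.frame from [run_pipeline()] (or any
#'   data.frame with an `E_volts` column).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (!"E_display" %in% names(results) && "E_volts" %in% names(results))
    results$E_display <- round_display(results$E_volts)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
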