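# Conformer selection and thermodynamic-cycle bookkeeping.
#
# Each candidate complex carries per-conformer energies of the free ligand
# in four states: "stable" (lowest-energy conformation in vacuum), "active"
# (the docked conformation re-optimized in vacuum), and their solvated
# counterparts "stable_solvated" and "active_solvated". Taking the lowest
# conformer energy as the state free energy and the solvated stable state
# as the reference, the "bonded" energy is
#   ddG(active_solvated) + e_dock
# where e_dock is the (supplied) docking energy. A negative bonded energy
# marks a thermochemically feasible complex; zero or positive marks an
# impossible one. All energies are carried in kcal/mol.

NF_STATES <- c("stable", "active", "stable_solvated", "active_solvated")

#' Construct a conformer energy table
#'
#' @param energies Data frame with columns \code{complex_id},
#'   \code{conformer_id}, \code{state} (one of \code{"stable"},
#'   \code{"active"}, \code{"stable_solvated"}, \code{"active_solvated"})
#'   and \code{energy} (kcal/mol); at most one row per (complex, conformer,
#'   state).
#' @param dock Data frame with columns \code{complex_id}, \code{e_dock}
#'   (kcal/mol); required for every complex carrying an
#'   \code{active_solvated} energy.
#' @return Object of class \code{energy_table}.
#' @export
energy_table <- function(energies, dock) {
  need_e <- c("complex_id", "conformer_id", "state", "energy")
  need_d <- c("complex_id", "e_dock")
  if (!all(need_e %in% names(energies)))
    stop_nodkey("energies need columns: ", paste(need_e, collapse = ", "))
  if (!all(need_d %in% names(dock)))
    stop_nodkey("dock table needs columns: ", paste(need_d, collapse = ", "))
  if (nrow(energies) == 0L) stop_nodkey("empty energy table")
  bad <- setdiff(unique(energies$state), NF_STATES)
  if (length(bad))
    stop_nodkey("unknown state(s): ", paste(bad, collapse = ", "))
  key <- paste(energies$complex_id, energies$conformer_id, energies$state)
  if (anyDuplicated(key))
    stop_nodkey("duplicate (complex, conformer, state) energy entries")
  if (anyDuplicated(dock$complex_id))
    stop_nodkey("duplicate docking energies")
  has_act <- unique(energies$complex_id[energies$state == "active_solvated"])
  no_dock <- setdiff(has_act, dock$complex_id)
  if (length(no_dock))
    stop_nodkey("missing docking energy for complex(es): ",
                paste(no_dock, collapse = ", "))
  structure(list(energies = as.data.frame(energies)[need_e],
                 dock = as.data.frame(dock)[need_d]),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat("Conformer energy table:",
      length(unique(x$energies$complex_id)), "complexes,",
      nrow(x$energies), "energy entries,",
      nrow(x$dock), "docking energies\n")
  invisible(x)
}

#' Select the lowest-energy conformers
#'
#' Ranks conformers by energy (ascending) and returns the ids of the
#' \code{min(k, n)} lowest; ties are broken by conformer id. This is the
#' ranking step of a hierarchical conformer screen (e.g. keep the 100
#' lowest from a force-field scan, then the 15 most stable after
#' refinement).
#'
#' @param energies Named numeric vector (names = conformer ids) or a data
#'   frame with columns \code{conformer_id}, \code{energy}.
#' @param k Number of conformers to keep (>= 1).
#' @return Character vector of conformer ids, most stable first.
#' @export
select_conformers <- function(energies, k) {
  if (k < 1) stop_nodkey("k must be >= 1")
  if (is.data.frame(energies)) {
    ids <- as.character(energies$conformer_id)
    e <- energies$energy
  } else {
    ids <- names(energies)
    e <- as.numeric(energies)
  }
  if (length(e) == 0L) stop_nodkey("empty conformer energy set")
  ord <- order(e, ids)
  ids[ord][seq_len(min(k, length(e)))]
}

#' Build the per-complex thermodynamic state ledger
#'
#' For every complex, the free energy of a state is the minimum over its
#' conformer energies; ddG subtracts the reference state; the bonded
#' energy adds the docking energy to ddG of the solvated active state.
#'
#' @param table An \code{\link{energy_table}}.
#' @param reference Reference state (default \code{"stable_solvated"}).
#' @return Object of class \code{state_ledger}: list with \code{states}
#'   (data frame: \code{complex_id}, \code{state}, \code{dG}, \code{ddG})
#'   and \code{complexes} (data frame: \code{complex_id}, \code{e_dock},
#'   \code{bonded}, \code{feasible}), plus the reference state name.
#' @export
build_ledger <- function(table, reference = "stable_solvated") {
  stopifnot(inherits(table, "energy_table"))
  if (!reference %in% NF_STATES)
    stop_nodkey("unknown reference state: ", reference)
  e <- table$energies
  cxs <- unique(e$complex_id)
  no_ref <- cxs[!cxs %in% e$complex_id[e$state == reference]]
  if (length(no_ref))
    stop_nodkey("missing reference state '", reference,
                "' for complex(es): ", paste(no_ref, collapse = ", "))
  dg <- stats::aggregate(energy ~ complex_id + state, data = e, FUN = min)
  names(dg)[3L] <- "dG"
  ref_dg <- dg$dG[dg$state == reference]
  names(ref_dg) <- dg$complex_id[dg$state == reference]
  dg$ddG <- dg$dG - ref_dg[dg$complex_id]
  dg <- dg[order(dg$complex_id, match(dg$state, NF_STATES)), ]
  rownames(dg) <- NULL

  act <- dg[dg$state == "active_solvated", c("complex_id", "ddG")]
  no_act <- setdiff(cxs, act$complex_id)
  if (length(no_act))
    stop_nodkey("missing active_solvated state for complex(es): ",
                paste(no_act, collapse = ", "))
  e_dock <- table$dock$e_dock[match(act$complex_id, table$dock$complex_id)]
  bonded <- act$ddG + e_dock
  structure(list(
    states = dg,
    complexes = data.frame(complex_id = act$complex_id, e_dock = e_dock,
                           bonded = bonded, feasible = bonded < 0),
    reference = reference
  ), class = "state_ledger")
}

#' @export
print.state_ledger <- function(x, ...) {
  cat("Thermochemical ledger (reference state: ", x$reference, ")\n",
      sep = "")
  df <- x$complexes
  df$bonded <- round(df$bonded, 3)
  print(df, row.names = FALSE)
  cat(sum(x$complexes$feasible), "of", nrow(x$complexes),
      "complexes thermochemically feasible (bonded < 0)\n")
  invisible(x)
}

#' Per-complex thermochemical verdict
#'
#' Feasible means strictly negative bonded energy; a bonded energy of
#' exactly zero is classified infeasible (no thermodynamic benefit).
#'
#' @param ledger A \code{\link{build_ledger}} result.
#' @return Named logical vector (names = complex ids).
#' @export
thermo_verdict <- function(ledger) {
  stopifnot(inherits(ledger, "state_ledger"))
  stats::setNames(ledger$complexes$feasible, ledger$complexes$complex_id)
}

#' Write a state ledger as TSV
#'
#' One row per complex and state with dG, ddG, and the complex-level
#' bonded energy and verdict repeated; energies in kcal/mol.
#'
#' @param ledger A \code{\link{state_ledger}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "state_ledger"))
  df <- merge(ledger$states, ledger$complexes, by = "complex_id")
  df <- df[order(df$complex_id, match(df$state, NF_STATES)),
           c("complex_id", "state", "dG", "ddG", "bonded", "feasible")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# energies in kcal/mol (conversion factors: 1 Hartree = 627.509 kcal/mol; 1 kJ/mol = 0.239006 kcal/mol)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conformer energy table and docking energies from TSV
#'
#' @param energies_path TSV with columns \code{complex_id},
#'   \code{conformer_id}, \code{state}, \code{energy_kcal_mol}.
#' @param dock_path TSV with columns \code{complex_id},
#'   \code{e_dock_kcal_mol}.
#' @return An \code{\link{energy_table}}.
#' @export
read_energy_table <- function(energies_path, dock_path) {
  e <- utils::read.delim(energies_path, stringsAsFactors = FALSE,
                         comment.char = "#")
  d <- utils::read.delim(dock_path, stringsAsFactors = FALSE,
                         comment.char = "#")
  if ("energy_kcal_mol" %in% names(e)) names(e)[names(e) == "energy_kcal_mol"] <- "energy"
  if ("e_dock_kcal_mol" %in% names(d)) names(d)[names(d) == "e_dock_kcal_mol"] <- "e_dock"
  energy_table(e, d)
}

#' Write a conformer energy table and docking energies as TSV
#'
#' @param table An \code{\link{energy_table}}.
#' @param energies_path,dock_path Output TSV paths.
#' @return Invisibly, the paths written.
#' @export
write_energy_table <- function(table, energies_path, dock_path) {
  stopifnot(inherits(table, "energy_table"))
  e <- table$energies; names(e)[names(e) == "energy"] <- "energy_kcal_mol"
  d <- table$dock; names(d)[names(d) == "e_dock"] <- "e_dock_kcal_mol"
  utils::write.table(e, energies_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(d, dock_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(energies_path, dock_path))
}
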