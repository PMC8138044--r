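# Synthetic conformer energy tables with planted feasibility.
#
# Energies are arbitrary planted numbers with controlled signs and ranks --
# no force field or solvation model is emulated. The sign of each complex's
# bonded energy is constructed, not sampled, so the realized feasible
# fraction equals the planted assignment exactly.

#' Simulate a conformer energy table with planted feasibility
#'
#' \code{round(fraction_feasible * n_complexes)} complexes (chosen by a
#' seeded permutation) are given a strictly negative bonded energy; the
#' rest strictly positive. Defaults mirror a screen of 8 docking-passed
#' complexes with 15 refined conformers each and 6 of 8 feasible.
#'
#' @param n_complexes Number of complexes (ids \code{CPX1...} unless
#'   \code{complex_ids} given).
#' @param n_conformers Conformers per complex and state.
#' @param fraction_feasible Planted fraction with negative bonded energy,
#'   in \code{[0, 1]}.
#' @param seed Master seed.
#' @param complex_ids Optional explicit complex ids.
#' @param feasible Optional explicit planted assignment (logical vector of
#'   length \code{n_complexes}); overrides \code{fraction_feasible}.
#' @return List with \code{table} (an \code{\link{energy_table}}) and
#'   \code{truth}: data frame of \code{complex_id}, \code{feasible},
#'   \code{bonded} (the planted bonded energy, kcal/mol).
#' @export
simulate_energy_table <- function(n_complexes = 8,
                                  n_conformers = 15,
                                  fraction_feasible = 0.75,
                                  seed = 1,
                                  complex_ids = NULL,
                                  feasible = NULL) {
  if (fraction_feasible < 0 || fraction_feasible > 1)
    stop_nodkey("fraction_feasible must lie in [0, 1]")
  stopifnot(n_complexes >= 1, n_conformers >= 1)
  ids <- complex_ids %||% sprintf("CPX%d", seq_len(n_complexes))
  stopifnot(length(ids) == n_complexes)
  n_feas <- round(fraction_feasible * n_complexes)

  feas <- if (!is.null(feasible)) {
    stopifnot(length(feasible) == n_complexes)
    as.logical(feasible)
  } else with_seed(derive_seed(seed, 0L), {
    f <- rep(FALSE, n_complexes)
    f[sample.int(n_complexes, n_feas)] <- TRUE
    f
  })

  built <- with_seed(derive_seed(seed, 1L), {
    rows <- list(); dock <- numeric(n_complexes); bonded <- numeric(n_complexes)
    for (i in seq_len(n_complexes)) {
      base <- stats::rnorm(1, mean = -1500, sd = 50)  # arbitrary scale
      d <- stats::runif(1, 8, 15)                     # |e_dock|
      b <- stats::runif(1, 1, 6)                      # |bonded|
      bonded[i] <- if (feas[i]) -b else b
      dock[i] <- -d
      # strain of the docked conformation over the solvated free minimum
      delta <- bonded[i] + d                          # > 0 either way
      mins <- c(stable = base + stats::runif(1, 5, 20),
                active = base + delta + stats::runif(1, 5, 20),
                stable_solvated = base,
                active_solvated = base + delta)
      for (st in NF_STATES) {
        offs <- c(0, sort(stats::runif(n_conformers - 1, 0.1, 25)))
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = ids[i],
          conformer_id = sprintf("c%02d", seq_len(n_conformers)),
          state = st, energy = mins[[st]] + offs)
      }
    }
    list(energies = do.call(rbind, rows),
         dock = data.frame(complex_id = ids, e_dock = dock),
         bonded = bonded)
  })

  list(table = energy_table(built$energies, built$dock),
       truth = data.frame(complex_id = ids, feasible = feas,
                          bonded = built$bonded))
}
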