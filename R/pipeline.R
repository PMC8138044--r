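# End-to-end orchestration from a YAML config.
#
# A run wires together: sequence polymorphism analysis, pose clustering,
# per-complex docking recognition (computed from structures or taken from
# labels), the thermochemical ledger (computed from energy tables or taken
# from labels), the external MD stability labels, and verdict composition.
# Every stage writes its TSV outputs; the run ends with verdicts.tsv, a
# machine-readable summary.json and a plain-text log of seeds and
# parameters.

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_nodkey("stage '", stage, "' failed: ", conditionMessage(e)))
}

# A stage's labels: "study" -> packaged fixture, otherwise a TSV path.
resolve_labels <- function(x, stage) {
  if (identical(x, "study")) study_labels(stage)
  else read_stage_labels(x, stage)
}

allele_letter <- c(Afghan = "A", Tajik = "T", European = "E")

#' Run the full screening pipeline from a config
#'
#' The config (YAML file or equivalent list) has blocks \code{alignment},
#' \code{poses}, \code{docking}, \code{md}, \code{thermo}, plus top-level
#' \code{seed} and \code{out}. Each data-bearing block either names input
#' files or a \code{simulate:} sub-block with generator parameters;
#' \code{docking}, \code{md} and \code{thermo} may instead name a
#' \code{labels:} TSV (\code{"study"} selects the packaged labels of the
#' pea screen). \code{docking: simulate: true} simulates one toy complex
#' per allele x NF-type pair (planted per the study docking outcomes) and
#' classifies it with \code{\link{recognize}}; \code{thermo: simulate:
#' true} simulates an energy table for the docking-passed complexes
#' (planted per the study thermo outcomes) and runs the ledger.
#'
#' @param config Path to a YAML file, or a list.
#' @param out_dir Output directory; defaults to \code{config$out}.
#' @return Invisibly, a list with \code{verdicts} (the
#'   \code{\link{compose_verdicts}} table), \code{summary} (its
#'   \code{summary()}) and \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_nodkey("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out
  if (is.null(out_dir)) stop_nodkey("no output directory ('out') configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log <- c(sprintf("nodkey pipeline run, seed %d", seed),
           sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  # --- sequence polymorphism -------------------------------------------
  if (!is.null(config$alignment)) {
    ca <- config$alignment
    stage_try("alignment", {
      aln <- if (!is.null(ca$simulate)) {
        args <- ca$simulate
        args$seed <- args$seed %||% derive_seed(seed, 10L)
        log <- c(log, paste("alignment: simulated,",
                             paste(names(args), unlist(args),
                                   sep = "=", collapse = " ")))
        do.call(simulate_alignment, args)$alignment
      } else {
        if (is.null(ca$fasta) || is.null(ca$groups))
          stop("needs 'fasta' and 'groups' (or a 'simulate' block)")
        log <- c(log, paste("alignment: files", ca$fasta, ca$groups))
        load_alignment(ca$fasta, ca$groups)
      }
      write_polymorphism_report(polymorphism_report(aln),
                                file.path(out_dir, "alignment"))
    })
  }

  # --- pose clustering --------------------------------------------------
  if (!is.null(config$poses)) {
    cp <- config$poses
    stage_try("poses", {
      poses <- if (!is.null(cp$simulate)) {
        args <- cp$simulate
        args$seed <- args$seed %||% derive_seed(seed, 20L)
        log <- c(log, paste("poses: simulated,",
                             paste(names(args), unlist(args),
                                   sep = "=", collapse = " ")))
        do.call(simulate_dimer_poses, args)$poses
      } else {
        if (is.null(cp$dir)) stop("needs 'dir' (or a 'simulate' block)")
        log <- c(log, paste("poses: directory", cp$dir))
        read_poses(cp$dir, ref_chain = cp$ref_chain %||% "A",
                   mob_chain = cp$mob_chain %||% "B")
      }
      sup <- superpose_poses(poses)
      sim <- similarity_matrix(sup, angle_max = cp$angle_max %||% 45,
                               corr_min = cp$corr_min %||% 0.5)
      cl <- find_clusters(sim, min_group = cp$min_group %||% 4)
      cl <- pick_representatives(cl, seed = derive_seed(seed, 21L))
      write_cluster_report(sim, cl, file.path(out_dir, "poses"))
    })
  }

  # --- docking recognition ---------------------------------------------
  if (is.null(config$docking))
    stop_nodkey("stage 'docking' failed: no docking block configured")
  docking <- stage_try("docking", {
    cd <- config$docking
    if (!is.null(cd$labels)) {
      log <- c(log, paste("docking: labels", cd$labels))
      res <- resolve_labels(cd$labels, "docking")
      attr(res, "provenance") <- "labeled"
      res
    } else if (isTRUE(cd$simulate)) {
      planted <- study_labels("docking")
      dir.create(file.path(out_dir, "recognition"), showWarnings = FALSE)
      rows <- lapply(seq_len(nrow(planted)), function(i) {
        sim <- simulate_complex(tail_in_pocket = planted$pass[i],
                                seed = derive_seed(seed, 30L + i))
        r <- recognize(sim$complex, sim$pocket)
        data.frame(allele = planted$allele[i], nf_type = planted$nf_type[i],
                   pass = r$recognized, tail_contacts = r$tail_contacts,
                   hbond_count = r$hbond_count)
      })
      rep_df <- do.call(rbind, rows)
      utils::write.table(rep_df,
                         file.path(out_dir, "recognition", "recognition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log <- c(log, "docking: recognition computed on simulated complexes")
      res <- rep_df[c("allele", "nf_type", "pass")]
      attr(res, "provenance") <- "computed"
      res
    } else stop("needs 'labels' or 'simulate: true'")
  })

  # --- MD stability labels ---------------------------------------------
  if (is.null(config$md))
    stop_nodkey("stage 'md' failed: no md block configured")
  md <- stage_try("md", {
    if (is.null(config$md$labels)) stop("needs 'labels'")
    log <- c(log, paste("md: labels", config$md$labels))
    resolve_labels(config$md$labels, "md")
  })

  # --- thermochemistry --------------------------------------------------
  if (is.null(config$thermo))
    stop_nodkey("stage 'thermo' failed: no thermo block configured")
  thermo <- stage_try("thermo", {
    ct <- config$thermo
    if (!is.null(ct$labels)) {
      log <- c(log, paste("thermo: labels", ct$labels))
      resolve_labels(ct$labels, "thermo")
    } else {
      tab <- if (isTRUE(ct$simulate)) {
        passed <- docking[docking$pass, ]
        planted <- study_labels("thermo")
        key <- paste(passed$allele, passed$nf_type)
        pl <- planted$pass[match(key, paste(planted$allele, planted$nf_type))]
        pl[is.na(pl)] <- TRUE
        log <- c(log, "thermo: ledger computed on simulated energy table")
        simulate_energy_table(
          n_complexes = nrow(passed), n_conformers = 15,
          seed = derive_seed(seed, 40L),
          complex_ids = paste(allele_letter[passed$allele], passed$nf_type,
                              sep = "-"),
          feasible = pl)$table
      } else if (!is.null(ct$energies) && !is.null(ct$dock)) {
        log <- c(log, paste("thermo: energy tables", ct$energies, ct$dock))
        read_energy_table(ct$energies, ct$dock)
      } else stop("needs 'labels', 'simulate: true', or 'energies' + 'dock'")
      ledger <- build_ledger(tab, reference = ct$reference %||%
                               "stable_solvated")
      dir.create(file.path(out_dir, "thermo"), showWarnings = FALSE)
      write_ledger(ledger, file.path(out_dir, "thermo", "ledger.tsv"))
      fl <- thermo_verdict(ledger)
      # complex ids are "<allele letter>-<NF type>"
      al <- names(allele_letter)[match(substr(names(fl), 1, 1),
                                       allele_letter)]
      data.frame(allele = al,
                 nf_type = sub("^[ATE]-", "", names(fl)),
                 pass = unname(fl))
    }
  })

  # --- composition ------------------------------------------------------
  verdicts <- stage_try("compose", {
    prov <- attr(docking, "provenance") %||% "labeled"
    compose_verdicts(docking, md, thermo, provenance = prov)
  })
  utils::write.table(verdicts, file.path(out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summary(verdicts)
  jsonlite::write_json(
    list(total = summ$total, docking_passed = summ$docking_passed,
         thermo_passed = summ$thermo_passed, md_passed = summ$md_passed,
         final_passed = summ$final_passed,
         final_by_allele = as.list(summ$final_by_allele)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(log, sprintf("final passes: %d of %d", summ$final_passed,
                            summ$total)),
             file.path(out_dir, "run_log.txt"))
  invisible(list(verdicts = verdicts, summary = summ, out_dir = out_dir))
}
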