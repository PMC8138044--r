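# Composition of per-complex stage verdicts.
#
# Each candidate complex (allele x Nod-factor type) passes three
# independent filters: docking recognition (fatty tail in the pocket), MD
# stability (an external trajectory label), and thermochemical feasibility
# (negative bonded energy). The final verdict is their conjunction; MD and
# thermo verdicts are only defined for docking-passed complexes.

NF_TYPES <- c("NF5Ac", "NF4Ac", "NF5NonAc", "NF4NonAc")

check_stage_table <- function(x, stage) {
  need <- c("allele", "nf_type", "pass")
  if (!all(need %in% names(x)))
    stop_nodkey(stage, " table needs columns: ", paste(need, collapse = ", "))
  x$pass <- as.logical(x$pass)
  if (anyDuplicated(paste(x$allele, x$nf_type)))
    stop_nodkey(stage, " table has duplicated (allele, nf_type) pairs")
  x
}

#' Compose docking, MD and thermochemistry verdicts
#'
#' @param docking Data frame with columns \code{allele}, \code{nf_type},
#'   \code{pass}; must contain exactly one row for every allele x NF-type
#'   combination (the full screen).
#' @param md_labels,thermo Data frames in the same format covering at
#'   least every docking-passed pair; rows for docking-failed pairs are
#'   ignored.
#' @param provenance \code{"labeled"} when stage outcomes come from
#'   external labels, \code{"computed"} when produced by this package's
#'   classifiers.
#' @return Object of class \code{verdict_table}: data frame with one row
#'   per (allele, nf_type) and columns \code{docking_pass}, \code{md_pass},
#'   \code{thermo_pass} (\code{NA} where docking failed),
#'   \code{final_pass}, \code{provenance}.
#' @export
compose_verdicts <- function(docking, md_labels, thermo,
                             provenance = "labeled") {
  docking <- check_stage_table(docking, "docking")
  md_labels <- check_stage_table(md_labels, "MD")
  thermo <- check_stage_table(thermo, "thermo")
  alleles <- unique(docking$allele)
  types <- unique(docking$nf_type)
  grid <- expand.grid(allele = alleles, nf_type = types,
                      stringsAsFactors = FALSE)
  missing <- setdiff(paste(grid$allele, grid$nf_type),
                     paste(docking$allele, docking$nf_type))
  if (length(missing))
    stop_nodkey("docking table does not cover pair(s): ",
                paste(missing, collapse = "; "))

  key <- function(x) paste(x$allele, x$nf_type)
  v <- docking[c("allele", "nf_type")]
  v$docking_pass <- docking$pass
  v$md_pass <- ifelse(v$docking_pass,
                      md_labels$pass[match(key(v), key(md_labels))], NA)
  v$thermo_pass <- ifelse(v$docking_pass,
                          thermo$pass[match(key(v), key(thermo))], NA)
  gaps <- v$docking_pass & (is.na(v$md_pass) | is.na(v$thermo_pass))
  if (any(gaps))
    stop_nodkey("missing MD or thermo verdict for docking-passed pair(s): ",
                paste(key(v)[gaps], collapse = "; "))
  v$final_pass <- v$docking_pass & !is.na(v$md_pass) & v$md_pass &
    !is.na(v$thermo_pass) & v$thermo_pass
  v$final_pass[!v$docking_pass] <- FALSE
  v$provenance <- provenance
  ord <- order(match(v$allele, c("Afghan", "Tajik", "European"), nomatch = 99),
               match(v$nf_type, NF_TYPES, nomatch = 99))
  v <- v[ord, ]
  rownames(v) <- NULL
  class(v) <- c("verdict_table", "data.frame")
  v
}

#' @export
print.verdict_table <- function(x, ...) {
  cat("Complex verdict table (", nrow(x), " allele x NF-type pairs)\n",
      sep = "")
  print.data.frame(x)
  cat("final passes:", sum(x$final_pass), "of", nrow(x), "\n")
  invisible(x)
}

#' Summarize a verdict table into per-stage counts
#'
#' @param object A \code{\link{compose_verdicts}} result.
#' @param ... Unused.
#' @return Object of class \code{summary.verdict_table}: list with
#'   \code{total}, \code{docking_passed}, \code{md_passed},
#'   \code{thermo_passed}, \code{final_passed} and \code{final_by_allele}
#'   (named integer vector).
#' @method summary verdict_table
#' @export
summary.verdict_table <- function(object, ...) {
  by_allele <- c(tapply(object$final_pass, object$allele, sum))
  storage.mode(by_allele) <- "integer"
  structure(list(
    total = nrow(object),
    docking_passed = sum(object$docking_pass),
    md_passed = sum(object$md_pass, na.rm = TRUE),
    thermo_passed = sum(object$thermo_pass, na.rm = TRUE),
    final_passed = sum(object$final_pass),
    final_by_allele = by_allele[order(names(by_allele))]
  ), class = "summary.verdict_table")
}

#' @export
print.summary.verdict_table <- function(x, ...) {
  cat("Screen summary:\n")
  cat("  complexes screened:        ", x$total, "\n")
  cat("  docking (pocket) passed:   ", x$docking_passed, "\n")
  cat("  thermochemistry passed:    ", x$thermo_passed, "\n")
  cat("  MD stability passed:       ", x$md_passed, "\n")
  cat("  final (all three) passed:  ", x$final_passed, "\n")
  cat("  final passes by allele:    ",
      paste(sprintf("%s %d", names(x$final_by_allele), x$final_by_allele),
            collapse = ", "), "\n")
  invisible(x)
}

#' Published stage labels of the pea LykX-Sym10 screen
#'
#' Per-(allele, NF-type) pass/fail outcomes of the three filters as
#' reported for the pea screen: acetylated NFs dock into all three dimers,
#' NF5NonAc only into the Tajik dimer and NF4NonAc only into the European
#' dimer (8 of 12); thermochemistry rejects the two four-sugar acetylated
#' complexes E-NF4Ac and A-NF4Ac; MD rejects T-NF5NonAc.
#'
#' @param stage One of \code{"docking"}, \code{"md"}, \code{"thermo"}.
#' @return Data frame with columns \code{allele}, \code{nf_type},
#'   \code{pass}.
#' @export
study_labels <- function(stage = c("docking", "md", "thermo")) {
  stage <- match.arg(stage)
  file <- c(docking = "docking_labels.tsv", md = "md_labels.tsv",
            thermo = "thermo_labels.tsv")[[stage]]
  path <- system.file("extdata", file, package = "nodkey")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a stage-label TSV
#'
#' @param path TSV with columns \code{allele}, \code{nf_type}, \code{pass}.
#' @param stage Stage name used in error messages.
#' @return Data frame.
#' @export
read_stage_labels <- function(path, stage = "stage") {
  if (!file.exists(path)) stop_nodkey(stage, " labels not found: ", path)
  check_stage_table(utils::read.delim(path, stringsAsFactors = FALSE), stage)
}
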