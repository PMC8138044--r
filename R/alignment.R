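# Segregating-polymorphism analysis of grouped amino-acid alignments.
#
# Receptor alleles (e.g. the Afghan, Tajik and European variants of the pea
# LykX receptor) are compared as pre-aligned ectodomain sequences carrying a
# group label. Columns that vary at all are "polymorphic"; columns whose
# per-group consensus residues disagree are "between-group" (segregating)
# sites, the candidate determinants of phenotype differences.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Construct a grouped amino-acid alignment
#'
#' @param sequences Character vector of equal-length amino-acid sequences
#'   (20-letter alphabet plus the gap character \code{"-"}).
#' @param ids Unique sequence identifiers; defaults to names of
#'   \code{sequences}.
#' @param groups Character vector mapping each sequence to its allele group
#'   (e.g. \code{"Afghan"}, \code{"Tajik"}, \code{"European"}); recycled
#'   names are not allowed, one label per sequence.
#' @return An object of class \code{allele_alignment}: a list with elements
#'   \code{sequences}, \code{ids}, \code{groups}.
#' @export
allele_alignment <- function(sequences, ids = names(sequences), groups) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop_nodkey("alignment is empty")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences))
    stop_nodkey("'ids' and 'sequences' lengths differ")
  if (anyDuplicated(ids))
    stop_nodkey("duplicated sequence id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]]
    stop_nodkey("sequences are not aligned (length mismatch): ",
                paste(bad, collapse = ", "))
  }
  if (length(groups) != length(sequences))
    stop_nodkey("'groups' must supply exactly one label per sequence")
  groups <- as.character(groups)
  structure(list(sequences = unname(sequences), ids = ids, groups = groups),
            class = "allele_alignment")
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat("Grouped amino-acid alignment:", length(x$ids), "sequences x",
      nchar(x$sequences[1L]), "columns\n")
  tab <- table(x$groups)
  cat("Groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a grouped alignment from FASTA plus a group table
#'
#' @param fasta_path Aligned amino-acid FASTA file.
#' @param groups_path Tab-separated table with columns \code{sequence_id}
#'   and \code{group}; every FASTA id must appear exactly once.
#' @return An \code{\link{allele_alignment}}.
#' @export
load_alignment <- function(fasta_path, groups_path) {
  if (!file.exists(fasta_path)) stop_nodkey("FASTA not found: ", fasta_path)
  if (!file.exists(groups_path)) stop_nodkey("group table not found: ", groups_path)
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  tab <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "group")
  if (!all(need %in% names(tab)))
    stop_nodkey("group table must have columns: ", paste(need, collapse = ", "))
  tab$sequence_id <- as.character(tab$sequence_id)
  unknown <- setdiff(tab$sequence_id, ids)
  if (length(unknown))
    stop_nodkey("group table id(s) not present in FASTA: ",
                paste(unknown, collapse = ", "))
  missing <- setdiff(ids, tab$sequence_id)
  if (length(missing))
    stop_nodkey("no group label for sequence id(s): ",
                paste(missing, collapse = ", "))
  groups <- tab$group[match(ids, tab$sequence_id)]
  allele_alignment(as.character(aa), ids = ids, groups = groups)
}

# Alignment as a character matrix, sequences in rows, columns 1-based.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$ids
  m
}

#' Polymorphic alignment columns
#'
#' A column is polymorphic if it carries at least two distinct symbols; the
#' gap \code{"-"} counts as a 21st symbol. Columns are reported 1-based so
#' they line up with residue labels such as #44.
#'
#' @param aln An \code{\link{allele_alignment}}.
#' @return Integer vector of 1-based column indices (possibly empty).
#' @export
polymorphic_sites <- function(aln) {
  stopifnot(inherits(aln, "allele_alignment"))
  m <- aln_matrix(aln)
  which(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

# Modal symbol of a character vector; ties broken alphabetically.
consensus_symbol <- function(col) {
  tab <- table(col)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1L]
}

#' Between-group (segregating) alignment columns
#'
#' Columns where the per-group consensus residues are not all identical.
#' The consensus of a group at a column is its modal residue, ties resolved
#' alphabetically, so minority within-group variation does not mask a
#' segregating site.
#'
#' @inheritParams polymorphic_sites
#' @return Integer vector of 1-based column indices.
#' @export
between_group_sites <- function(aln) {
  stopifnot(inherits(aln, "allele_alignment"))
  grps <- unique(aln$groups)
  if (length(grps) < 2L) return(integer(0))
  m <- aln_matrix(aln)
  cons <- vapply(grps, function(g) {
    apply(m[aln$groups == g, , drop = FALSE], 2L, consensus_symbol)
  }, character(ncol(m)))
  which(apply(cons, 1L, function(r) length(unique(r)) > 1L))
}

#' Mean pairwise sequence difference
#'
#' Average Hamming distance (number of differing columns, gaps counted as a
#' symbol) over all unordered sequence pairs.
#'
#' @inheritParams polymorphic_sites
#' @return A single number in \code{[0, alignment length]}.
#' @export
mean_pairwise_difference <- function(aln) {
  stopifnot(inherits(aln, "allele_alignment"))
  n <- length(aln$sequences)
  if (n < 2L) stop_nodkey("need at least two sequences")
  m <- aln_matrix(aln)
  # per column: number of differing pairs = (n^2 - sum of class sizes^2) / 2
  diff_pairs <- sum(apply(m, 2L, function(col) {
    cs <- table(col)
    (n^2 - sum(cs^2)) / 2
  }))
  diff_pairs / (n * (n - 1) / 2)
}

#' Most frequent full-length sequence within a group
#'
#' Ties are broken by first occurrence in the alignment order.
#'
#' @inheritParams polymorphic_sites
#' @param group Group label.
#' @return The modal sequence (character scalar) with its id as name.
#' @export
modal_sequence <- function(aln, group) {
  stopifnot(inherits(aln, "allele_alignment"))
  if (!group %in% aln$groups) stop_nodkey("unknown group: ", group)
  idx <- which(aln$groups == group)
  seqs <- aln$sequences[idx]
  uniq <- unique(seqs)                      # preserves first-occurrence order
  counts <- vapply(uniq, function(s) sum(seqs == s), integer(1))
  win <- uniq[which.max(counts)]            # which.max takes the first max
  stats::setNames(win, aln$ids[idx[match(win, seqs)]])
}

#' Full polymorphism report for a grouped alignment
#'
#' @inheritParams polymorphic_sites
#' @return Object of class \code{polymorphism_report} with elements
#'   \code{polymorphic_sites}, \code{between_group_sites},
#'   \code{mean_pairwise_diff} and \code{modal_sequences} (named by group).
#' @export
polymorphism_report <- function(aln) {
  stopifnot(inherits(aln, "allele_alignment"))
  grps <- unique(aln$groups)
  modal <- vapply(grps, function(g) unname(modal_sequence(aln, g)),
                  character(1))
  structure(list(
    polymorphic_sites  = polymorphic_sites(aln),
    between_group_sites = between_group_sites(aln),
    mean_pairwise_diff = if (length(aln$sequences) > 1L)
      mean_pairwise_difference(aln) else 0,
    modal_sequences = modal,
    n_sequences = length(aln$sequences),
    length = nchar(aln$sequences[1L])
  ), class = "polymorphism_report")
}

#' @export
print.polymorphism_report <- function(x, ...) {
  cat("Polymorphism report (", x$n_sequences, " sequences x ", x$length,
      " columns)\n", sep = "")
  cat("  polymorphic sites:   ", length(x$polymorphic_sites),
      if (length(x$polymorphic_sites) <= 30)
        paste0("  [", paste(x$polymorphic_sites, collapse = ", "), "]")
      else "", "\n", sep = "")
  cat("  between-group sites: ", length(x$between_group_sites),
      if (length(x$between_group_sites))
        paste0("  [", paste(x$between_group_sites, collapse = ", "), "]")
      else "", "\n", sep = "")
  cat("  mean pairwise difference: ",
      format(x$mean_pairwise_diff, digits = 3), " residues\n", sep = "")
  invisible(x)
}

#' Write a polymorphism report and modal sequences to disk
#'
#' Writes \code{polymorphism.tsv} (section, value rows) and
#' \code{modal_sequences.fasta} into \code{dir}.
#'
#' @param report A \code{\link{polymorphism_report}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_polymorphism_report <- function(report, dir) {
  stopifnot(inherits(report, "polymorphism_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "polymorphism.tsv")
  df <- rbind(
    data.frame(section = "polymorphic_site",
               value = as.character(report$polymorphic_sites)),
    data.frame(section = "between_group_site",
               value = as.character(report$between_group_sites)),
    data.frame(section = "mean_pairwise_diff",
               value = format(report$mean_pairwise_diff, digits = 10))
  )
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fas <- file.path(dir, "modal_sequences.fasta")
  set <- Biostrings::AAStringSet(report$modal_sequences)
  names(set) <- names(report$modal_sequences)
  Biostrings::writeXStringSet(set, fas)
  invisible(c(tsv, fas))
}
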