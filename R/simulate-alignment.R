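# Synthetic grouped alignments with planted polymorphism.
#
# Emulates an allele-sequence study: three allele groups of an ectodomain
# alignment, a handful of group-diagnostic (between-group) columns, and a
# larger set of columns that vary only within one group. Defaults mirror a
# receptor survey of 95 sequences (5 + 2 + 88 across three allele groups,
# 212 columns, 4 diagnostic sites among 23 polymorphic ones).

#' Simulate a grouped alignment with planted polymorphic columns
#'
#' Between-group columns get a consensus residue per group (not all equal,
#' shared by every member of the group). Within-group columns plant a
#' strict-minority variant inside one group of size >= 3, so the group
#' consensus is unchanged and the column is polymorphic but not segregating.
#' All remaining columns are monomorphic.
#'
#' @param n_groups Number of allele groups (labels \code{group1...} unless
#'   \code{group_names} given).
#' @param seqs_per_group Integer vector (length \code{n_groups}) of group
#'   sizes.
#' @param length Alignment length in columns.
#' @param n_between_sites Planted group-diagnostic columns.
#' @param n_within_sites Planted within-group-variable columns; requires at
#'   least one group of size >= 3.
#' @param seed Master seed; planted positions and residue draws use
#'   deterministic sub-streams, so two runs with the same seed are
#'   byte-identical.
#' @param residue_seed Optional override for the residue-draw sub-stream;
#'   with the same \code{seed} but different \code{residue_seed}, planted
#'   positions are identical while residues differ.
#' @param group_names Optional group labels.
#' @return List with \code{alignment} (an \code{\link{allele_alignment}})
#'   and \code{truth}: planted \code{between_sites}, \code{within_sites}
#'   (sorted 1-based columns) and the per-group consensus residues at the
#'   between-sites.
#' @export
simulate_alignment <- function(n_groups = 3,
                               seqs_per_group = c(5, 2, 88),
                               length = 212,
                               n_between_sites = 4,
                               n_within_sites = 19,
                               seed = 1,
                               residue_seed = NULL,
                               group_names = c("Afghan", "Tajik", "European")[seq_len(n_groups)]) {
  if (length(seqs_per_group) == 1L)
    seqs_per_group <- rep(seqs_per_group, n_groups)
  stopifnot(length(seqs_per_group) == n_groups, all(seqs_per_group >= 1))
  if (n_between_sites + n_within_sites > length)
    stop_nodkey("planted site counts exceed alignment length")
  if (n_within_sites > 0 && !any(seqs_per_group >= 3))
    stop_nodkey("within-group variation needs a group of size >= 3 ",
                "(strict minority below a stable consensus)")
  if (is.null(group_names)) group_names <- paste0("group", seq_len(n_groups))

  aa20 <- setdiff(AA_ALPHABET, "-")
  n_total <- sum(seqs_per_group)
  groups <- rep(group_names, times = seqs_per_group)
  ids <- sprintf("%s_%02d", abbreviate(groups, 3), stats::ave(
    seq_len(n_total), groups, FUN = seq_along))

  pos_seed <- derive_seed(seed, 0L)
  res_seed <- if (is.null(residue_seed)) derive_seed(seed, 1L)
              else as.integer(residue_seed)

  planted <- with_seed(pos_seed, sample.int(length, n_between_sites + n_within_sites))
  between <- sort(planted[seq_len(n_between_sites)])
  within <- sort(setdiff(planted, between))

  m <- with_seed(res_seed, {
    backbone <- sample(aa20, length, replace = TRUE)
    m <- matrix(rep(backbone, each = n_total), nrow = n_total)
    cons_tab <- NULL
    if (n_between_sites > 0) {
      cons_tab <- matrix("", n_groups, n_between_sites,
                         dimnames = list(group_names, as.character(between)))
      for (j in seq_along(between)) {
        # per-group consensus residues, guaranteed not all identical
        repeat {
          res <- sample(aa20, n_groups, replace = TRUE)
          if (length(unique(res)) > 1L) break
        }
        cons_tab[, j] <- res
        m[, between[j]] <- rep(res, times = seqs_per_group)
      }
    }
    eligible <- which(seqs_per_group >= 3)
    for (col in within) {
      g <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      rows <- which(groups == group_names[g])
      n_var <- sample.int(ceiling(length(rows) / 2) - 1L, 1L)
      carriers <- if (length(rows) == n_var) rows else sample(rows, n_var)
      variant <- sample(setdiff(aa20, m[rows[1L], col]), 1L)
      m[carriers, col] <- variant
    }
    attr(m, "cons_tab") <- cons_tab
    m
  })

  aln <- allele_alignment(apply(m, 1L, paste, collapse = ""),
                          ids = ids, groups = groups)
  list(alignment = aln,
       truth = list(between_sites = between, within_sites = within,
                    between_consensus = attr(m, "cons_tab")))
}

#' Write a grouped alignment as FASTA plus a group table
#'
#' @param aln An \code{\link{allele_alignment}}.
#' @param fasta_path Output FASTA path.
#' @param groups_path Output TSV path (columns \code{sequence_id},
#'   \code{group}).
#' @return Invisibly, the paths written.
#' @export
write_alignment <- function(aln, fasta_path, groups_path) {
  stopifnot(inherits(aln, "allele_alignment"))
  set <- Biostrings::AAStringSet(aln$sequences)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, fasta_path)
  utils::write.table(
    data.frame(sequence_id = aln$ids, group = aln$groups),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, groups_path))
}
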