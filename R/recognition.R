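# Geometric ligand-recognition classification.
#
# A heterodimer pose "recognizes" a Nod factor when the fatty-acyl tail sits
# in the inter-subunit hydrophobic pocket: at least min_tail_contacts tail
# heavy atoms within a van-der-Waals contact cutoff of pocket-residue heavy
# atoms. Hydrogen bonds between ligand and protein polar atoms are counted
# as a diagnostic and can optionally gate the verdict.

LIGAND_PARTS <- c("core", "tail", "acetyl")

#' Construct a protein-ligand complex structure
#'
#' @param protein Data frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{elesy}, \code{x}, \code{y}, \code{z}
#'   (coordinates in Angstroms).
#' @param ligand Data frame with columns \code{atom_id}, \code{elesy},
#'   \code{part} (one of \code{"core"}, \code{"tail"}, \code{"acetyl"}),
#'   \code{x}, \code{y}, \code{z}.
#' @return Object of class \code{nf_complex}.
#' @export
nf_complex <- function(protein, ligand) {
  need_p <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  need_l <- c("atom_id", "elesy", "part", "x", "y", "z")
  if (!all(need_p %in% names(protein)))
    stop_nodkey("protein table needs columns: ", paste(need_p, collapse = ", "))
  if (!all(need_l %in% names(ligand)))
    stop_nodkey("ligand table needs columns: ", paste(need_l, collapse = ", "))
  if (nrow(ligand) == 0L) stop_nodkey("complex has no ligand atoms")
  if (anyDuplicated(ligand$atom_id))
    stop_nodkey("duplicated ligand atom id(s): ",
                paste(unique(ligand$atom_id[duplicated(ligand$atom_id)]),
                      collapse = ", "))
  bad <- setdiff(unique(ligand$part), LIGAND_PARTS)
  if (length(bad))
    stop_nodkey("unknown ligand part label(s): ", paste(bad, collapse = ", "))
  structure(list(protein = as.data.frame(protein)[need_p],
                 ligand = as.data.frame(ligand)[need_l]),
            class = "nf_complex")
}

#' @export
print.nf_complex <- function(x, ...) {
  cat("Protein-ligand complex:", nrow(x$protein), "protein atoms (chains",
      paste(unique(x$protein$chain), collapse = ", "), "),",
      nrow(x$ligand), "ligand atoms\n")
  cat("  ligand parts:",
      paste(sprintf("%s (%d)", names(table(x$ligand$part)),
                    table(x$ligand$part)), collapse = ", "), "\n")
  invisible(x)
}

protein_xyz <- function(cx, rows = TRUE)
  as.matrix(cx$protein[rows, c("x", "y", "z"), drop = FALSE])
ligand_xyz <- function(cx, rows = TRUE)
  as.matrix(cx$ligand[rows, c("x", "y", "z"), drop = FALSE])

#' Define the inter-subunit hydrophobic pocket
#'
#' @param residues Data frame with columns \code{chain}, \code{resno} and
#'   optionally \code{resid}.
#' @param cutoff Heavy-atom contact cutoff, Angstroms (default 4.5, the
#'   usual van-der-Waals contact range).
#' @param min_tail_contacts Tail atoms in contact required for pocket
#'   occupancy (default 3).
#' @return Object of class \code{pocket_definition}.
#' @export
pocket_definition <- function(residues, cutoff = 4.5, min_tail_contacts = 3) {
  if (!all(c("chain", "resno") %in% names(residues)))
    stop_nodkey("pocket residues need columns chain, resno")
  if (nrow(residues) == 0L) stop_nodkey("pocket definition is empty")
  if (cutoff <= 0) stop_nodkey("cutoff must be positive")
  structure(list(residues = as.data.frame(residues), cutoff = cutoff,
                 min_tail_contacts = min_tail_contacts),
            class = "pocket_definition")
}

#' Default LykX-Sym10 fatty-tail pocket
#'
#' The inter-subunit hydrophobic pocket: Val37, Met38, Pro39, Ala40, Phe41,
#' Leu42, Leu43, Tyr119 and Ala121 of the LykX subunit (chain A) and Val217
#' and Phe218 of the Sym10 subunit (chain B).
#'
#' @inheritParams pocket_definition
#' @return A \code{\link{pocket_definition}}.
#' @export
lykx_sym10_pocket <- function(cutoff = 4.5, min_tail_contacts = 3) {
  path <- system.file("extdata", "pocket_residues.tsv", package = "nodkey")
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  pocket_definition(res, cutoff = cutoff,
                    min_tail_contacts = min_tail_contacts)
}

# Rows of cx$protein belonging to the pocket; errors on missing residues.
pocket_rows <- function(cx, pocket) {
  key <- paste(cx$protein$chain, cx$protein$resno)
  want <- paste(pocket$residues$chain, pocket$residues$resno)
  missing <- setdiff(want, key)
  if (length(missing))
    stop_nodkey("pocket residue(s) absent from structure: ",
                paste(missing, collapse = "; "))
  key %in% want
}

#' Count fatty-tail atoms in contact with the pocket
#'
#' Number of tail-part ligand heavy atoms within the pocket's contact
#' cutoff of any heavy atom of any pocket residue. Hydrogens are excluded
#' on both sides.
#'
#' @param cx An \code{\link{nf_complex}}.
#' @param pocket A \code{\link{pocket_definition}}.
#' @param cutoff Optional cutoff override (Angstroms).
#' @return Integer contact count.
#' @export
tail_pocket_contacts <- function(cx, pocket = lykx_sym10_pocket(),
                                 cutoff = pocket$cutoff) {
  stopifnot(inherits(cx, "nf_complex"), inherits(pocket, "pocket_definition"))
  rows <- pocket_rows(cx, pocket) & cx$protein$elesy != "H"
  tail <- cx$ligand$part == "tail" & cx$ligand$elesy != "H"
  if (!any(tail) || !any(rows)) return(0L)
  d <- cross_dist(ligand_xyz(cx, tail), protein_xyz(cx, rows))
  sum(apply(d, 1L, min) <= cutoff)
}

#' Count protein-ligand hydrogen bonds
#'
#' Donor/acceptor heavy atoms are the nitrogens and oxygens of either
#' partner. A protein-ligand N/O pair within \code{d_max} counts as one
#' bond; when explicit hydrogens are present and one is covalently attached
#' (within 1.3 Angstroms) to either heavy atom, the D-H...A angle must also
#' reach \code{angle_min}. Structures without hydrogens are judged on
#' distance alone.
#'
#' @param cx An \code{\link{nf_complex}}.
#' @param d_max Heavy-atom donor-acceptor distance cutoff, Angstroms.
#' @param angle_min Minimum D-H...A angle, degrees.
#' @return Integer bond count.
#' @export
count_hydrogen_bonds <- function(cx, d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(cx, "nf_complex"))
  pp <- cx$protein$elesy %in% c("N", "O")
  lp <- cx$ligand$elesy %in% c("N", "O")
  if (!any(pp) || !any(lp)) return(0L)
  pxyz <- protein_xyz(cx, pp); lxyz <- ligand_xyz(cx, lp)
  d <- cross_dist(lxyz, pxyz)
  pairs <- which(d <= d_max, arr.ind = TRUE)
  if (!nrow(pairs)) return(0L)
  hxyz <- rbind(protein_xyz(cx, cx$protein$elesy == "H"),
                ligand_xyz(cx, cx$ligand$elesy == "H"))
  if (nrow(hxyz) == 0L) return(nrow(pairs))
  ok <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- lxyz[pairs[k, 1L], ]; b <- pxyz[pairs[k, 2L], ]
    hd <- cross_dist(hxyz, rbind(a, b))
    att <- which(hd[, 1L] <= 1.3 | hd[, 2L] <= 1.3)
    if (!length(att)) return(TRUE)              # no hydrogen on this pair
    any(vapply(att, function(i) {
      h <- hxyz[i, ]
      don <- if (hd[i, 1L] <= 1.3) a else b     # heavy atom owning the H
      acc <- if (hd[i, 1L] <= 1.3) b else a
      u <- don - h; v <- acc - h
      ang <- acos(min(1, max(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      ang >= angle_min
    }, logical(1)))
  }, logical(1))
  sum(ok)
}

#' Residues in contact with the ligand
#'
#' Protein residues having at least one heavy atom within \code{cutoff} of
#' any ligand heavy atom, with the number of contacting atom pairs per
#' residue, sorted by chain then residue number.
#'
#' @param cx An \code{\link{nf_complex}}.
#' @param cutoff Contact cutoff, Angstroms (default 4.0).
#' @return Data frame with columns \code{chain}, \code{resno}, \code{resid},
#'   \code{contacts}.
#' @export
contact_residues <- function(cx, cutoff = 4.0) {
  stopifnot(inherits(cx, "nf_complex"))
  heavy_p <- cx$protein$elesy != "H"
  heavy_l <- cx$ligand$elesy != "H"
  empty <- data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), contacts = integer(0))
  if (!any(heavy_p) || !any(heavy_l)) return(empty)
  d <- cross_dist(protein_xyz(cx, heavy_p), ligand_xyz(cx, heavy_l))
  n_contact <- rowSums(d <= cutoff)
  prot <- cx$protein[heavy_p, ]
  keep <- n_contact > 0
  if (!any(keep)) return(empty)
  agg <- stats::aggregate(
    n_contact[keep],
    by = list(chain = prot$chain[keep], resno = prot$resno[keep],
              resid = prot$resid[keep]),
    FUN = sum)
  names(agg)[4L] <- "contacts"
  agg <- agg[order(agg$chain, agg$resno), c("chain", "resno", "resid",
                                            "contacts")]
  rownames(agg) <- NULL
  agg
}

#' Classify ligand recognition by a dimer pose
#'
#' The stated criterion is pocket occupancy: the complex is recognized when
#' at least \code{min_tail_contacts} fatty-tail atoms contact the
#' hydrophobic pocket. Hydrogen bonds are always counted and reported; by
#' default they do not gate the verdict (\code{min_hbonds = 0}).
#'
#' @param cx An \code{\link{nf_complex}}.
#' @param pocket A \code{\link{pocket_definition}}.
#' @param min_tail_contacts Required tail-pocket contacts; defaults to the
#'   pocket definition's value.
#' @param min_hbonds Required protein-ligand hydrogen bonds (default 0).
#' @param hbond_d_max,hbond_angle_min Hydrogen-bond geometry, see
#'   \code{\link{count_hydrogen_bonds}}.
#' @return Object of class \code{recognition_result}: list with
#'   \code{recognized}, \code{tail_contacts}, \code{hbond_count},
#'   \code{contact_residues}.
#' @export
recognize <- function(cx, pocket = lykx_sym10_pocket(),
                      min_tail_contacts = pocket$min_tail_contacts,
                      min_hbonds = 0,
                      hbond_d_max = 3.5, hbond_angle_min = 120) {
  tc <- tail_pocket_contacts(cx, pocket)
  hb <- count_hydrogen_bonds(cx, d_max = hbond_d_max,
                             angle_min = hbond_angle_min)
  structure(list(
    recognized = tc >= min_tail_contacts && hb >= min_hbonds,
    tail_contacts = tc,
    hbond_count = hb,
    contact_residues = contact_residues(cx)
  ), class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat("Ligand recognition:", if (x$recognized) "RECOGNIZED" else "not recognized",
      "\n  tail-pocket contacts:", x$tail_contacts,
      "\n  protein-ligand hydrogen bonds:", x$hbond_count,
      "\n  contacting residues:", nrow(x$contact_residues), "\n")
  invisible(x)
}

#' Write a complex as PDB plus a ligand-annotation table
#'
#' Protein atoms are written as ATOM records on their chains; ligand atoms
#' as HETATM records on chain X (residue NDF). The annotation TSV maps each
#' ligand \code{atom_id} to its \code{part}.
#'
#' @param cx An \code{\link{nf_complex}}.
#' @param pdb_path,annot_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_complex <- function(cx, pdb_path, annot_path) {
  stopifnot(inherits(cx, "nf_complex"))
  p <- cx$protein; l <- cx$ligand
  n <- nrow(p) + nrow(l)
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(as.matrix(rbind(p[c("x", "y", "z")],
                                       l[c("x", "y", "z")])))),
    type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
    resno = c(p$resno, rep(1L, nrow(l))),
    resid = c(p$resid, rep("NDF", nrow(l))),
    eleno = seq_len(n),
    elety = c(p$elety, l$atom_id),
    chain = c(p$chain, rep("X", nrow(l))),
    elesy = c(p$elesy, l$elesy))
  utils::write.table(data.frame(atom_id = l$atom_id, part = l$part),
                     annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pdb_path, annot_path))
}

#' Read a complex from PDB plus a ligand-annotation table
#'
#' @param pdb_path PDB file: protein chains as ATOM records, the ligand as
#'   HETATM records.
#' @param annot_path TSV with columns \code{atom_id}, \code{part} covering
#'   every ligand atom exactly once.
#' @return An \code{\link{nf_complex}}.
#' @export
load_complex <- function(pdb_path, annot_path) {
  if (!file.exists(pdb_path)) stop_nodkey("PDB not found: ", pdb_path)
  if (!file.exists(annot_path))
    stop_nodkey("ligand annotation not found: ", annot_path)
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  is_lig <- at$type == "HETATM"
  if (!any(is_lig)) stop_nodkey("no HETATM ligand records in ", pdb_path)
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  if (!all(c("atom_id", "part") %in% names(annot)))
    stop_nodkey("annotation needs columns atom_id, part")
  if (anyDuplicated(annot$atom_id))
    stop_nodkey("duplicated atom id(s) in annotation: ",
                paste(unique(annot$atom_id[duplicated(annot$atom_id)]),
                      collapse = ", "))
  lig <- at[is_lig, ]
  lig_ids <- trimws(lig$elety)
  unannot <- setdiff(lig_ids, annot$atom_id)
  if (length(unannot))
    stop_nodkey("ligand atom(s) without part annotation: ",
                paste(unannot, collapse = ", "))
  prot <- at[!is_lig, ]
  elesy_p <- trimws(prot$elesy)
  elesy_p[elesy_p == ""] <- substr(trimws(prot$elety)[elesy_p == ""], 1, 1)
  elesy_l <- trimws(lig$elesy)
  elesy_l[elesy_l == ""] <- substr(lig_ids[elesy_l == ""], 1, 1)
  nf_complex(
    protein = data.frame(chain = prot$chain, resno = prot$resno,
                         resid = trimws(prot$resid),
                         elety = trimws(prot$elety), elesy = elesy_p,
                         x = prot$x, y = prot$y, z = prot$z),
    ligand = data.frame(atom_id = lig_ids, elesy = elesy_l,
                        part = annot$part[match(lig_ids, annot$atom_id)],
                        x = lig$x, y = lig$y, z = lig$z))
}
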