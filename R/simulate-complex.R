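# Toy protein-ligand complexes with planted recognition truth.
#
# The pseudo-proteins are alanine-like residues carrying only backbone N,
# CA, C, O atoms -- the minimal set supporting centroids, contacts and
# hydrogen-bond geometry. The hydrophobic pocket is a two-chain ring of the
# eleven canonical pocket residues around the z axis; a "threaded" fatty
# tail runs along that axis, an "out" tail is displaced 25 Angstroms away.
# Hydrogen-bond sites are isolated rim residues whose backbone N faces a
# planted ligand oxygen at 2.9 Angstroms, with every other polar atom kept
# beyond the 3.5 Angstrom cutoff, so the planted bond count is exact.

# Backbone atoms for one pseudo-residue: CA at ca, C/O offset along unit
# vector out (plus a perpendicular nudge), N along n_dir (defaults to out).
pseudo_residue <- function(chain, resno, resid, ca, out, perp = c(0, 0, 1),
                           n_dir = out) {
  pos <- rbind(N  = ca + 1.46 * n_dir,
               CA = ca,
               C  = ca + 2.40 * out + 0.50 * perp,
               O  = ca + 3.00 * out - 0.50 * perp)
  data.frame(chain = chain, resno = resno, resid = resid,
             elety = rownames(pos),
             elesy = c("N", "C", "C", "O"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Simulate a toy complex with planted recognition outcome
#'
#' @param pocket_radius Radius (Angstroms) of the pocket-residue ring
#'   around the tail axis; must stay below about 4.3 so a threaded tail is
#'   within the default 4.5 contact cutoff.
#' @param tail_in_pocket Plant the fatty tail inside (\code{TRUE}) or 25
#'   Angstroms away from (\code{FALSE}) the pocket.
#' @param n_tail_atoms Tail carbon atoms (>= 3).
#' @param n_hbond_pairs Planted protein-ligand hydrogen bonds (>= 0).
#' @param seed Seed for the small coordinate jitter (0.05 Angstroms) that
#'   keeps structures from being perfectly symmetric.
#' @return List with \code{complex} (an \code{\link{nf_complex}}),
#'   \code{pocket} (the matching \code{\link{pocket_definition}}) and
#'   \code{truth} (\code{recognized}, \code{hbond_pairs}).
#' @export
simulate_complex <- function(pocket_radius = 4.0,
                             tail_in_pocket = TRUE,
                             n_tail_atoms = 8,
                             n_hbond_pairs = 4,
                             seed = 1) {
  if (n_tail_atoms < 3) stop_nodkey("n_tail_atoms must be >= 3")
  if (n_hbond_pairs < 0) stop_nodkey("n_hbond_pairs must be >= 0")
  if (pocket_radius <= 2 || pocket_radius > 4.3)
    stop_nodkey("pocket_radius must lie in (2, 4.3] Angstroms")

  pocket_res <- utils::read.delim(
    system.file("extdata", "pocket_residues.tsv", package = "nodkey"),
    stringsAsFactors = FALSE)
  n_pock <- nrow(pocket_res)
  ring_z <- rep(c(0, 1.5, 3.0), length.out = n_pock)
  prot <- do.call(rbind, lapply(seq_len(n_pock), function(i) {
    th <- 2 * pi * (i - 1) / n_pock
    out <- c(cos(th), sin(th), 0)
    pseudo_residue(pocket_res$chain[i], pocket_res$resno[i],
                   pocket_res$resid[i],
                   ca = pocket_radius * out + c(0, 0, ring_z[i]), out = out)
  }))

  # isolated hydrogen-bond rim: backbone N faces the ligand oxygen site
  if (n_hbond_pairs > 0) {
    rim <- do.call(rbind, lapply(seq_len(n_hbond_pairs), function(k) {
      n_pos <- c(10 * k, 20, 0)
      pseudo_residue("A", 45L + k, "ASN",
                     ca = n_pos + c(0, 1.46, 0), out = c(0, 1, 0),
                     perp = c(1, 0, 0), n_dir = c(0, -1, 0))
    }))
    prot <- rbind(prot, rim)
  }

  tail_shift <- if (tail_in_pocket) c(0, 0, 0) else c(25, 0, 0)
  tail <- data.frame(
    atom_id = sprintf("T%d", seq_len(n_tail_atoms)), elesy = "C",
    part = "tail",
    x = tail_shift[1], y = tail_shift[2],
    z = tail_shift[3] - 0.5 + 0.9 * (seq_len(n_tail_atoms) - 1))
  # each rim residue's backbone N sits at y = 20; its partner oxygen 2.9 below
  core_o <- if (n_hbond_pairs > 0) data.frame(
    atom_id = sprintf("O%d", seq_len(n_hbond_pairs)), elesy = "O",
    part = "core",
    x = 10 * seq_len(n_hbond_pairs), y = 20 - 2.9, z = 0)
    else NULL
  core_c <- data.frame(
    atom_id = sprintf("C%d", 1:3), elesy = "C", part = "core",
    x = c(5, 15, 25), y = 14, z = 0)
  acetyl <- data.frame(
    atom_id = c("A1", "A2"), elesy = "C", part = "acetyl",
    x = c(-5, -6.3), y = 14, z = 0)
  lig <- rbind(tail, core_o, core_c, acetyl)

  jit <- function(df, sd = 0.05) {
    df[c("x", "y", "z")] <- df[c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(df), sd = sd), ncol = 3)
    df
  }
  with_seed(derive_seed(seed, 0L), {
    prot <- jit(prot)
    lig <- jit(lig)
  })

  list(complex = nf_complex(prot, lig),
       pocket = pocket_definition(pocket_res),
       truth = list(recognized = tail_in_pocket,
                    hbond_pairs = n_hbond_pairs))
}
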