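# Geometric ligand-recognition: pocket contacts, hydrogen bonds, verdicts.

# Minimal hand-made complex: one pocket residue at the origin region and a
# configurable ligand.
tiny_complex <- function(lig) {
  prot <- data.frame(
    chain = "A", resno = 37L, resid = "VAL",
    elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
    x = c(0, 1.5, 3.0, 4.2), y = 0, z = 0)
  nf_complex(prot, lig)
}
lig_row <- function(id, elesy, part, x, y = 0, z = 0)
  data.frame(atom_id = id, elesy = elesy, part = part, x = x, y = y, z = z)
tiny_pocket <- pocket_definition(data.frame(chain = "A", resno = 37L),
                                 cutoff = 4.5, min_tail_contacts = 1)

test_that("tail_pocket_contacts counts tail atoms near pocket residues", {
  # tail 20 Angstroms away -> no contacts
  cx <- tiny_complex(lig_row("T1", "C", "tail", x = 20))
  expect_equal(tail_pocket_contacts(cx, tiny_pocket), 0L)
  # two tail atoms in range, one out; core atoms never count
  cx2 <- tiny_complex(rbind(lig_row("T1", "C", "tail", x = 0, y = 3),
                            lig_row("T2", "C", "tail", x = 1.5, y = 4),
                            lig_row("T3", "C", "tail", x = 0, y = 8),
                            lig_row("C1", "C", "core", x = 0, y = 2)))
  expect_equal(tail_pocket_contacts(cx2, tiny_pocket), 2L)
  # vanishing cutoff
  expect_equal(tail_pocket_contacts(cx2, tiny_pocket, cutoff = 0.1), 0L)
  # missing pocket residue is an error naming it
  bad <- pocket_definition(data.frame(chain = "A", resno = c(37L, 99L)))
  expect_error(tail_pocket_contacts(cx2, bad), "A 99")
})

test_that("tail_pocket_contacts equals a brute-force distance scan and is monotone", {
  for (seed in 1:10) {
    sim <- simulate_complex(tail_in_pocket = (seed %% 2 == 0), seed = seed)
    cx <- sim$complex
    rows <- paste(cx$protein$chain, cx$protein$resno) %in%
      paste(sim$pocket$residues$chain, sim$pocket$residues$resno)
    pxyz <- as.matrix(cx$protein[rows, c("x", "y", "z")])
    tail <- cx$ligand[cx$ligand$part == "tail", ]
    counts <- vapply(c(3, 4.5, 6), function(cut) {
      hits <- 0L
      for (i in seq_len(nrow(tail))) {
        dmin <- min(sqrt(colSums((t(pxyz) -
                                    as.numeric(tail[i, c("x", "y", "z")]))^2)))
        if (dmin <= cut) hits <- hits + 1L
      }
      expect_equal(tail_pocket_contacts(cx, sim$pocket, cutoff = cut), hits)
      hits
    }, integer(1))
    expect_true(all(diff(counts) >= 0))   # monotone in cutoff
  }
})

test_that("count_hydrogen_bonds applies distance and angle criteria", {
  # no polar ligand atoms
  expect_equal(count_hydrogen_bonds(
    tiny_complex(lig_row("C1", "C", "core", x = 2))), 0L)
  # one O...N pair at 2.9 Angstroms (no explicit hydrogens: distance only)
  cx <- tiny_complex(lig_row("O1", "O", "core", x = -2.9))
  expect_equal(count_hydrogen_bonds(cx), 1L)
  # beyond the 3.5 cutoff
  expect_equal(count_hydrogen_bonds(
    tiny_complex(lig_row("O1", "O", "core", x = -3.6))), 0L)
  # explicit hydrogen at a favourable angle (donor O-H...N, ~160 degrees)
  h <- lig_row("H1", "H", "core", x = -1.99, y = 0.25)
  cx_good <- tiny_complex(rbind(lig_row("O1", "O", "core", x = -2.9), h))
  expect_equal(count_hydrogen_bonds(cx_good), 1L)
  # hydrogen pointing away: D-H...A angle far below 120 -> rejected
  h_bad <- lig_row("H1", "H", "core", x = -3.9)
  cx_bad <- tiny_complex(rbind(lig_row("O1", "O", "core", x = -2.9), h_bad))
  expect_equal(count_hydrogen_bonds(cx_bad), 0L)
  # monotonicity in the distance cutoff and in the angle threshold
  expect_equal(count_hydrogen_bonds(cx, d_max = 2.0), 0L)
  expect_equal(count_hydrogen_bonds(cx_bad, angle_min = 0), 1L)
})

test_that("contact_residues reports residues by distance, sorted", {
  # ligand far away -> empty
  far <- tiny_complex(lig_row("C1", "C", "core", x = 30))
  expect_equal(nrow(contact_residues(far)), 0L)
  # three residues at 3.2 / 3.8 / 4.5 from the ligand atom: two pass at 4.0
  prot <- do.call(rbind, lapply(seq_along(c(3.2, 3.8, 4.5)), function(i) {
    data.frame(chain = "A", resno = 10L + i, resid = "GLY", elety = "CA",
               elesy = "C", x = c(3.2, 3.8, 4.5)[i], y = 0, z = 0)
  }))
  cx <- nf_complex(prot, lig_row("C1", "C", "core", x = 0))
  cr <- contact_residues(cx, cutoff = 4.0)
  expect_equal(cr$resno, c(11L, 12L))
  expect_equal(cr$contacts, c(1L, 1L))
  cr2 <- contact_residues(cx, cutoff = 5.0)
  expect_equal(cr2$resno, c(11L, 12L, 13L))
})

test_that("recognize combines pocket occupancy and the optional H-bond gate", {
  cin <- simulate_complex(tail_in_pocket = TRUE, n_hbond_pairs = 3, seed = 1)
  r <- recognize(cin$complex, cin$pocket)
  expect_true(r$recognized)
  expect_gte(r$tail_contacts, 3)
  expect_equal(r$hbond_count, 3L)
  # requiring 4 bonds on a 3-bond complex flips the verdict
  r4 <- recognize(cin$complex, cin$pocket, min_hbonds = 4)
  expect_false(r4$recognized)
  cout <- simulate_complex(tail_in_pocket = FALSE, seed = 1)
  expect_false(recognize(cout$complex, cout$pocket)$recognized)
  expect_output(print(r), "RECOGNIZED")
})

test_that("recognition outputs are invariant under global rigid transforms", {
  set.seed(21)
  sim <- simulate_complex(tail_in_pocket = TRUE, n_hbond_pairs = 2, seed = 8)
  r0 <- recognize(sim$complex, sim$pocket)
  for (i in 1:5) {
    cx <- transform_complex(sim$complex, random_rigid_transform())
    r <- recognize(cx, sim$pocket)
    expect_identical(r$recognized, r0$recognized)
    expect_identical(r$tail_contacts, r0$tail_contacts)
    expect_identical(r$hbond_count, r0$hbond_count)
    expect_identical(r$contact_residues$resno, r0$contact_residues$resno)
  }
})

test_that("load_complex validates ligand annotation", {
  d <- withr::local_tempdir()
  sim <- simulate_complex(seed = 2)
  pdb <- file.path(d, "c.pdb"); an <- file.path(d, "c.tsv")
  write_complex(sim$complex, pdb, an)

  annot <- read.delim(an)
  # annotation missing one atom
  write.table(annot[-1, ], file.path(d, "miss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_complex(pdb, file.path(d, "miss.tsv")),
               annot$atom_id[1])
  # duplicated atom id
  write.table(rbind(annot, annot[1, ]), file.path(d, "dup.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_complex(pdb, file.path(d, "dup.tsv")), "duplicated")
  # structure without a ligand
  prot_only <- sim$complex$protein
  bio3d::write.pdb(file = file.path(d, "p.pdb"),
                   xyz = as.numeric(t(as.matrix(prot_only[c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(prot_only)),
                   resno = prot_only$resno, resid = prot_only$resid,
                   eleno = seq_len(nrow(prot_only)),
                   elety = prot_only$elety, chain = prot_only$chain)
  expect_error(load_complex(file.path(d, "p.pdb"), an), "HETATM")
})

test_that("the default pocket matches the canonical residue list", {
  pk <- lykx_sym10_pocket()
  expect_equal(nrow(pk$residues), 11L)
  expect_setequal(pk$residues$resno[pk$residues$chain == "A"],
                  c(37:43, 119, 121))
  expect_setequal(pk$residues$resno[pk$residues$chain == "B"], c(217, 218))
  expect_equal(pk$cutoff, 4.5)
})
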