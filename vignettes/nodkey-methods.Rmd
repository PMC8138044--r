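---
title: "Screening Nod-factor recognition by LysM receptor heterodimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening Nod-factor recognition by LysM receptor heterodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodkey)
```

## The scientific problem

Rhizobia signal their legume hosts with Nod factors (NFs):
lipochitooligosaccharides built from 3–5 N-acetylglucosamine units carrying
a fatty-acyl tail and small decorations such as an acetyl group. Perception
is by heterodimeric pairs of LysM receptor-like kinases. In pea, the
candidate pair is LykX (a LYR-class subunit and the likely *Sym2*
specificity determinant) together with Sym10 (the LYK-class subunit).
Three LykX allele groups — Afghan, Tajik and European — differ in a handful
of amino acids, and correspondingly in phenotype: Afghanistan-type peas
nodulate only with strains producing acetylated NFs, European-type peas
also accept non-acetylated NFs.

`nodkey` implements the decision layer of an *in silico* screen of this
system: which NF variants does each allelic heterodimer recognize, and is
that recognition physically plausible? The heavy molecular-engine stages —
homology modelling, docking, molecular dynamics (MD), quantum-chemical
energy evaluation — are deliberately outside the package. Their outputs
enter as coordinates, energy tables and pass/fail labels; `nodkey` owns
everything downstream: the statistics, the geometry, the bookkeeping and
the composed verdict. A synthetic-data module generates all of these
inputs with planted ground truth, so the full pipeline is testable without
any external software or downloads.

## Segregating-polymorphism analysis

Allele sequences arrive as a pre-aligned amino-acid FASTA (alignment
itself is an upstream tool's job) plus a sequence-to-group table. The
module reports:

* **polymorphic sites** — 1-based columns with at least two distinct
  symbols; the gap `-` counts as a 21st symbol. Columns are numbered in
  the alignment frame so they line up with residue labels such as #44;
  mapping to a precursor numbering is left to the user.
* **between-group (segregating) sites** — columns where per-group
  consensus residues disagree. The consensus is the modal residue, ties
  broken alphabetically, so minority within-group variation cannot mask or
  fake a segregating site. A site perfectly segregating in consensus but
  with a few within-group exceptions still counts: requiring perfect
  segregation would make the statistic brittle under sequencing noise.
* **mean pairwise difference** — average Hamming distance over all
  unordered pairs, computed columnwise in closed form and verified in
  tests against a brute-force double loop.
* **modal sequences** — the most frequent full-length sequence per group
  (ties to first occurrence), the natural choice of a single
  representative structure per allele for modelling.

## Pose clustering

Protein-protein docking yields tens of rigid heterodimer poses per allele
(the emulated survey uses 30 per allele, 90 in all). Poses are first
placed in a common frame by Procrustes superposition of their LykX
subunits: a least-squares rotation plus translation with **no scaling and
no reflection** (the rotation determinant is forced to +1 by
sign-correcting the smallest singular direction; collinear reference
atoms raise an error rather than risking a reflected fit, since a
reflection is not a rigid motion of a protein).

After superposition the common frame is **canonicalized** from the
reference subunit's own geometry: centroid at the origin, principal axes
as coordinate axes, the sign of each axis fixed by the third moment of the
point cloud along it, and the third axis completed by a cross product so
the frame is right-handed. This matters because one of the two similarity
measures below is a per-axis correlation, which is not rotation-invariant;
anchoring the axes in the cloud's internal geometry makes every reported
measure independent of the arbitrary frame the PDB files arrived in.

Two poses are similar when **both**:

* the angle at the LykX centroid between the directions to their two
  Sym10 centroids is **strictly below 45°**, and
* the minimum over X/Y/Z of the Pearson correlations between their Sym10
  coordinates (atom-by-atom, identical ordering required) is **strictly
  above 0.5**.

The strict inequalities follow the natural reading of "lower than" /
"higher than". A zero-variance axis (possible only in degenerate toys)
yields correlation 1 against another constant axis and 0 otherwise, with a
warning. Both measures are symmetric, and the operation is agnostic to the
atom set supplied (Cα-only or all-atom) — the choice is the caller's,
since practice varies and the fixtures use Cα.

Clusters are **maximal cliques of at least four pairwise-similar poses**
("pairwise similar" rules out connected-component clustering), found with
igraph's clique enumeration and then merged whenever two cliques share a
pose, until the clusters are disjoint. Poses in no sufficient clique stay
unclustered. The whole procedure is checked against a hand-written
Bron–Kerbosch-plus-union-find oracle on a thousand random instances of up
to 12 poses. One representative pose per cluster is drawn uniformly at
random under a per-cluster seed derived deterministically from the master
seed.

## Geometric recognition

A heterodimer pose *recognizes* a NF when the fatty-acyl tail sits in the
inter-subunit hydrophobic pocket — the packaged default pocket is Val37,
Met38, Pro39, Ala40, Phe41, Leu42, Leu43, Tyr119 and Ala121 of LykX plus
Val217 and Phe218 of Sym10. The criterion is qualitative in origin, so the
numeric thresholds are declared package defaults, not inherited numbers:

* tail-pocket contact: heavy-atom distance ≤ **4.5 Å** (standard
  van-der-Waals contact range), requiring ≥ **3** tail atoms in contact;
* hydrogen bonds: donor/acceptor N or O heavy atoms within **3.5 Å**,
  plus a D–H···A angle ≥ **120°** whenever explicit hydrogens are present
  (distance-only otherwise — docked heavy-atom models rarely carry
  protons);
* `min_hbonds` defaults to **0**: pocket occupancy alone decides
  recognition, because the screen this emulates accepted a complex with
  only three hydrogen bonds at the docking stage. The bond count is always
  reported as a diagnostic, and the gate can be raised (e.g.
  `min_hbonds = 4`) to explore the stricter rule.

Ligand atoms are partitioned into `core` / `tail` / `acetyl` by an
explicit annotation table rather than chemical perception: the NF is a
nonstandard heteromolecule and guessing its topology from a PDB would be
fragile. Contact residues are reported with per-residue contact-pair
counts at a separate 4.0 Å cutoff. All outputs are invariant under global
rigid motion of the complex, and both counters are monotone in their
cutoffs — properties the test suite verifies directly.

## Thermochemical bookkeeping

Conformer screening is a ranking problem: keep the `k` lowest-energy
conformers (ties to the lower id), used twice in the emulated protocol —
100 survivors of a force-field scan, then the 15 most stable refined
conformers. The thermodynamic cycle tracks the free ligand in four states:
`stable` and `active` (lowest-energy vs docked-then-reoptimized
conformation, in vacuum) and their solvated counterparts. Per complex:

* ΔG(state) = minimum conformer energy of that state (the cycle compares
  *lowest* energies; a Boltzmann average over conformers would be a
  defensible extension but is not what the bookkeeping models);
* ΔΔG(state) = ΔG(state) − ΔG(stable_solvated), the solvated stable state
  being the reference — its ΔΔG is identically zero;
* bonded = ΔΔG(active_solvated) + e_dock, where e_dock is the supplied
  docking energy, treated as an opaque number in kcal/mol;
* **feasible ⇔ bonded < 0**. Exactly zero is classified infeasible: with
  no thermodynamic benefit there is no driving force for complex
  formation, so the conservative call is rejection.

Energies are carried in kcal/mol throughout; the ledger TSV header records
the conversion factors for inputs arriving in Hartree or kJ/mol. ΔΔG and
the verdict are invariant to per-complex constant offsets, conformer
order, and insertion of dominated conformers — all exercised in tests.

## Verdict composition

Each (allele × NF-type) complex passes through three independent filters:
docking recognition, MD stability and thermochemical feasibility. MD
stability is consumed as an external boolean label — trajectory analysis
is out of scope — and the packaged labels encode the published outcomes of
the pea screen, including its single MD failure (T-NF5NonAc, whose tail
left the pocket). The final verdict is the conjunction; MD and thermo
fields of docking-failed complexes are undefined (`NA`) rather than
false-by-construction, since those filters were never run on them. On the
packaged labels the stages pass 8 → 6 (thermo) and 7 (MD) of 8, composing
to 5 final passes of 12: European {NF5Ac, NF4NonAc}, Tajik {NF5Ac, NF4Ac},
Afghan {NF5Ac} — the pattern that mirrors the known symbiotic phenotypes.

`run_pipeline()` drives everything from a YAML config: each stage block
names input files, a `labels:` source (`"study"` selects the packaged
labels), or a `simulate:` block; outputs are TSV tables, a JSON summary
and a run log recording seeds and parameters. Stage failures abort with
the stage name. Because this is a library-style analysis package, the
exported functions and `run_pipeline()` are the interface; there is no
shell executable.

## The synthetic-data module

The generators are first-class, tested code, and their defaults are the
emulated study's conditions:

* **Alignments** — 95 sequences of length 212 in three groups (5 Afghan,
  2 Tajik, 88 European; the published survey's group sizes are internally
  inconsistent, so the remainder was assigned to the largest group), with
  4 planted group-diagnostic columns and 19 within-group-variable columns
  (23 polymorphic in all). Between-columns give every member of a group
  its group's consensus residue, consensus residues not all equal across
  groups; within-columns plant a strict-minority variant inside one group
  of size ≥ 3, so group consensus is unchanged. Minority carrier counts
  are drawn uniformly below half the host group, which on the default
  survey yields a mean pairwise difference of roughly 4–5 residues —
  the realistic range for a low-divergence allele survey. All other
  columns are monomorphic, so planted truth is recoverable exactly.
* **Pose families** — one shared reference subunit; each cluster's mobile
  subunit shares a rigid placement plus isotropic Gaussian atom noise
  (single Å-scale knob). Placement directions are rejection-sampled to
  pairwise angles above 55° (the 45° threshold plus a 10° margin), which
  guarantees separability; each pose is then shipped in its own random
  rigid frame so superposition is genuinely exercised. Subunits are
  Gaussian point clouds (default 30 atoms, 5 Å spread, mobile centroid
  30 Å out) — adequate for centroid, correlation and superposition
  geometry, with none of a real fold's structure.
* **Toy complexes** — alanine-like pseudo-residues (backbone N, CA, C, O
  only). The pocket is a ring of the eleven canonical residues around the
  z axis (default radius 4.0 Å) with the tail threaded along the axis, or
  displaced 25 Å when planting a non-recognized complex. Hydrogen-bond
  sites are isolated rim residues whose backbone N faces a ligand oxygen
  at 2.9 Å with every other polar atom kept beyond 3.5 Å, so planted bond
  counts are exact. A 0.05 Å jitter keeps structures from being perfectly
  symmetric without threatening any margin.
* **Energy tables** — planted numbers with controlled signs: the bonded
  energy's sign is constructed per complex (defaults: 8 complexes, 15
  conformers, feasible fraction 0.75), so the realized feasible fraction
  equals the planted assignment exactly. No force field or solvation
  model is emulated.

Every generator maps one master seed through fixed sub-stream derivation
(an affine hash below 2³¹), so runs are byte-identical under the same seed
and, e.g., residue draws can change while planted positions stay fixed.

What passing on this synthetic suite does **not** show: that the numeric
defaults are optimal for real structures (real pockets are not rings, real
alignments have alignment error, real energy tables carry correlated
noise), nor anything about the upstream engines. What it does show is that
the decision layer — the statistics, geometry, bookkeeping and
composition — is correct wherever the truth is known.

## Numerical choices and limitations

* Superposition refuses collinear/coincident reference atoms (singular
  value ratio below 1e-8) instead of returning an ill-determined or
  reflected fit.
* Tie-breaks are deterministic everywhere: alphabetical for consensus
  residues, first-occurrence for modal sequences, lexicographic for
  conformer ranking.
* Angle computations clamp cosines to [−1, 1] before `acos`.
* Problem sizes in tests and the acceptance script (e.g. 1000 clustering
  oracle instances of ≤ 12 poses, 100-seed recovery sweeps, 50-complex
  recognition panels) were chosen to exercise the combinatorics densely
  while keeping a full run in well under a minute on one core.
* The package makes no claim about pea biology beyond reproducing the
  screen's decision logic; in particular the residue-numbering frame of
  the polymorphic sites, the physical realism of toy complexes, and the
  meaning of e_dock (ligand-dimer vs including the protein-protein term)
  are all inherited from the inputs, not resolved here.
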