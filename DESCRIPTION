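Package: nodkey
Title: Nod Factor Recognition Screening for LysM Receptor Heterodimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening which Nod factor (lipochitooligosaccharide)
    variants are recognized by candidate LysM receptor-like kinase
    heterodimers, modelled on the pea LykX-Sym10 system. Implements
    segregating amino-acid polymorphism analysis of allele groups,
    clustering of protein-protein docking poses by centroid-angle and
    per-axis correlation after rigid Procrustes superposition, a geometric
    ligand-recognition classifier (fatty-acyl tail occupancy of the
    inter-subunit hydrophobic pocket plus hydrogen-bond counting),
    conformer selection and thermodynamic-cycle free-energy bookkeeping
    over supplied energy tables, and composition of per-complex verdicts
    from docking, molecular-dynamics stability and thermochemical filters.
    A synthetic-data module generates all pipeline inputs with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
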