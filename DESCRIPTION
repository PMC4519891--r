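Package: fccfold
Title: Multi-Objective Protein Structure Prediction on the FCC Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio protein structure prediction on the 3-D face-centered
    cubic (FCC) lattice. Conformations are self-avoiding walks over the 12
    FCC directions, scored by contact-based statistical energies (the
    hydrophobic-polar model and arbitrary 20x20 contact potentials) and by an
    empirical backbone (kappa, alpha) virtual-bond angle preference term.
    Structures are optimized with single-objective genetic algorithms or with
    the multi-objective NSGA and NSGA-II engines, using rotation-based
    crossover, generalized pull moves, and K-site mutation; predictions are
    compared to reference structures by distance-matrix RMSD. Ships the
    binned angle-preference matrix and the CB513-derived benchmark identifier
    list as packaged data, plus readers and writers for FASTA, C-alpha PDB,
    contact-potential tables, and move-string files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
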