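Package: pbdock
Title: Grid-Based Ligand Docking with Poisson-Boltzmann and Coulomb
    Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rigid-body protein-ligand docking and scoring built around
    pre-computed receptor interaction grids. Ligand poses are initialized
    by Gaussian shape-and-charge overlay onto a reference ligand (Hodgkin
    similarity) and refined by global minimization of a force-field
    binding energy with a soft-core Lennard-Jones term. Electrostatics
    can be scored with a distance-dependent-dielectric Coulomb potential
    or with a finite-difference linearized Poisson-Boltzmann potential
    map (with two-step focusing and OpenDX map interchange). Includes
    TRIPOS MOL2 input/output with AMBER-style van der Waals parameter
    assignment, all-atom and symmetry-corrected RMSD, ROC and adjusted
    LogAUC enrichment metrics, and seeded synthetic fixture generators
    (pockets, ligands, active/decoy screening sets) so the whole
    pipeline is testable without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
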