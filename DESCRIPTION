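Package: clasp
Title: Catalytic Active Site Prediction by Spatial and Electrostatic Congruence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate catalytic sites in protein structures by
    matching ordered three-dimensional active-site motifs under
    stereochemical residue grouping, then pruning and ranking matches by
    congruence of inter-residue electrostatic potential differences.
    Potentials are obtained from a finite-difference solution of the
    linearized Poisson-Boltzmann equation on a cubic lattice with a
    two-dielectric (solute/solvent) medium, reported in units of kT/e.
    Includes motif extraction from Catalytic Site Atlas listings, an
    exhaustive pruned congruence search with a brute-force oracle,
    classification metrics and ROC sweeps, and deterministic synthetic
    fixture generators (toy structures, point-charge systems, labelled
    score sets) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
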