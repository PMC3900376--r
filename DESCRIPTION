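Package: fdanet
Title: Force Distribution Analysis of Molecular Ensembles
Version: 0.1.0
Authors@R: person("FDA", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Detects allosteric signaling pathways in proteins by monitoring
    changes in pairwise inter-atomic forces between two states of a molecular
    ensemble (force distribution analysis). Computes per-frame pairwise forces
    over bonds, angles, dihedrals, Coulomb and Lennard-Jones terms, averages
    them over replica trajectories, differences a ligand-free (apo) and a
    ligand-bound (holo) state, derives per-atom punctual stress, extracts the
    largest connected component of the force-difference network above a force
    cutoff, and traces source-to-hinge pathways. Includes hinge bending-angle
    profiles with error propagation, geometric hydrogen-bond detection,
    least-squares superposition, and a seeded two-domain bead-model generator
    with a designed binding-site-to-hinge force pathway that provides ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
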