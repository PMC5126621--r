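Package: pocketmc
Title: Monte Carlo Refinement and Binding-Energy Analysis of
    Protein-Ligand Pocket Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iterative Metropolis Monte Carlo refinement of
    protein-cofactor-ligand complexes with simulated annealing, backbone
    small/shear moves, rotamer repacking and quasi-Newton (DFP)
    minimisation; a four-term docking-style scoring function
    (Lennard-Jones, distance-dielectric Coulomb, directional hydrogen
    bond, torsion prior); a binding-energy ladder E_bind = E_complex -
    (E_ref + E_lig) with productive/unproductive pose classification;
    LigPlot-style interaction fingerprints; and a synthetic mini-pocket
    generator with property-matched decoy ligands for end-to-end
    validation of the protocol (pose recovery and decoy-ligand
    discrimination).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
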