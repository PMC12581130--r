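Package: qzipper
Title: Idealized PolyQ Cross-Beta Fibril Models and Aggregation Kinetics
Version: 0.1.0
Authors@R: person("qzipper", "maintainers", email = "qzipper@example.org",
    role = c("aut", "cre"))
Description: Tools for studying polyglutamine (polyQ) amyloid aggregation at
    the desk scale. Builds idealized beta-turn and beta-arc cross-beta
    steric-zipper fibril lattices from ssNMR-derived glutamine conformer
    dihedrals and validates them with circular dihedral statistics,
    Kabsch-Sander secondary-structure assignment, sheet/strand spacing and
    end-to-end conformer classification. Learns residue-level native-contact
    maps from conformational ensembles and merges them into a multi-state
    Go-type interaction table with flanking-domain cross-contacts treated as
    excluded volume. Computes aggregation-kinetics statistics (chain
    clustering, monomer and largest-cluster fractions, half-times,
    oligomer-order distributions) and ships a synthetic-data generator:
    random-coil ensembles, perturbed fibrils, and an exact stochastic
    (Gillespie) dock-and-lock aggregation model with two docking channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
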