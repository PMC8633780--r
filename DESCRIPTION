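Package: flexrig
Title: Rigidity, Elastic Network Modes and Geometric Simulation of Protein Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-network analysis of protein crystal structures: detection of
    covalent bonds, hydrogen bonds and salt bridges with Mayo-form effective energies,
    and hydrophobic tethers; body-bar (6,6) pebble-game rigidity analysis with rigid
    cluster decomposition and rigidity dilution over an energy cut-off series, in both
    an ambient regime and a cold regime with weakened hydrophobic tethers; one-node-
    per-residue anisotropic elastic network models with analytic rigid-body modes and
    low-frequency modes by deflated inverse iteration; and geometric simulation of
    flexible motion that biases an all-atom structure along a normal-mode direction
    while restoring bonding and steric geometry by constraint projection. Includes the
    surrounding structural statistics (Kabsch RMSD, ensemble RMSF, B-factor profiling,
    Shrake-Rupley SASA and interface area, residue composition and salt-bridge
    censuses) and deterministic synthetic fixtures (ideal helices, packed dimers,
    random body-bar multigraphs) so every algorithm is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
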