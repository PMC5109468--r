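Package: scvar
Title: Quantifying Protein Side-Chain Conformational Variability
Version: 0.1.0
Authors@R: person("scvar", "maintainers", email = "scvar@example.org", role = c("aut", "cre"))
Description: Tools to quantify side-chain conformational variability in
    protein crystal structures: PDB parsing with full alternate-location
    (altloc) fidelity, chi dihedral measurement and comparison under a
    30-degree change rule with symmetric-residue flipping, electron-density
    reliability classification from sigma-normalized CCP4/MRC maps,
    Shrake-Rupley solvent accessibility, a survey engine for conformational
    variation across altloc states, chains and crystals, a density-aware
    multi-conformer assessment scheme for side-chain prediction, and a
    synthetic-structure generator with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
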