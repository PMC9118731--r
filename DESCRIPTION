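Package: ankthermo
Title: Thermodynamic Sensor Analysis of the Notch-1 Ankyrin Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the computational case that the ankyrin
    (ANK) domain of the Notch-1 receptor acts as a cellular thermodynamic
    sensor. Segments ankyrin domains into 33-residue repeats and profiles
    per-element amino-acid composition; re-implements a Boltzmann-inverted
    pairwise interaction potential and a windowed intrinsic-disorder score;
    derives the disorder-based destabilization coefficient, dissociation
    temperature thresholds and the cellular heat-budget spike; computes
    screened-Coulomb surface electrostatics with charged-patch detection and
    acidic-residue geometry; inventories interface hydrogen bonds of the
    Notch transcription complex; simulates a charged coupled-oscillator
    chain (Langevin dynamics) standing in for temperature-dependent
    molecular dynamics; and provides qPCR Pfaffl-ratio, amplification
    efficiency and molecular-beacon hairpin melting-temperature arithmetic.
    Includes seed-deterministic synthetic-structure generators so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
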