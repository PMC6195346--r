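Package: ionbarrier
Title: Barrier-Model Analysis of Ligand-Gated Anion Channel Permeation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rate-theory analysis of ion permeation through ligand-gated
    anion channels such as the calcium-activated chloride channel TMEM16A.
    Fits a minimal three-barrier Eyring permeation model to instantaneous
    current-voltage relations from excised-patch recordings, extracts
    relative barrier-crossing rates and their modulation by intracellular
    divalent cations via Hill analysis, converts rates to activation-energy
    differences and relates them to binding-site valence through Coulombic
    fits yielding effective dielectric constants, evaluates double-mutant
    cycle coupling energies, and decomposes whole-patch current-voltage
    curves into open states of differing calcium occupancy by non-negative
    least squares. Includes a synthetic inside-out-patch data generator
    (voltage-step protocols, rundown, leak, noise) with recorded ground
    truth for recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
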