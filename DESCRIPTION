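Package: serpinfold
Title: Consensus Serpin Design and Protein Folding Biophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for consensus protein design from serpin multiple
    sequence alignments and for the biophysical characterisation of the
    designed proteins: two-state equilibrium unfolding by the linear
    extrapolation method, stopped-flow folding kinetics with chevron
    analysis and a ground-state-switch intermediate model, variable
    temperature circular dichroism melt fitting, serpin stoichiometry of
    inhibition arithmetic, and comparative structural metrics (hydrogen
    bonds, salt bridges, accessible surface area, solvent-inaccessible
    cavities, backbone RMSD). Ships a deterministic synthetic-data
    generator with named presets so every analysis stage can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
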