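Package: lobescope
Title: Quantitative Structural Analysis of Capsid-Homology Lobe Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative structural biology of small
    alpha-helical capsid-homology (lobe) domains and their oligomers:
    rigid-body superposition and RMSD (Kabsch), Shrake-Rupley solvent
    accessible surface area and dimer-interface analysis (buried surface
    area, hydrogen bonds, salt bridges, nonpolar contacts), helix-axis and
    crossing-angle geometry, global sequence alignment with EMBOSS-style
    percent identity, multiple-sequence-alignment redundancy pruning and
    log-base-20 entropy conservation profiles mapped onto structures,
    small-angle X-ray scattering utilities (Debye intensity, Guinier fit,
    pair-distance distribution, model-to-data scaling), and consensus
    oligomeric-state calling from heterogeneous molar-mass estimates.
    Includes seeded synthetic-data generators (ideal helices, helix dimers,
    alignments with controlled entropy and redundancy, noisy scattering
    curves) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
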