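Package: epimap
Title: Structure-Based Mapping of Conformational and Linear Allergen Epitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural immunoinformatics of allergen isoforms:
    Shrake-Rupley solvent accessible surface area with Gly-X-Gly relative
    normalisation, a three-rule conformational B-cell epitope predictor
    operating on protein structures, Wu-Kabat alignment variability and
    epitope-variant enumeration, sliding-window antigenicity profiles
    (Kyte-Doolittle, Welling, Parker) with high-antigenicity region calling,
    Kabsch superposition and alignment-mapped C-alpha RMSD, cysteine
    disulfide feasibility screening, sequence formal-charge summaries,
    linear-versus-conformational epitope overlap classification, and seeded
    synthetic structure/alignment generators with machine-readable ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
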