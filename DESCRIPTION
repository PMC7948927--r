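Package: mdvar
Title: Classifying Protein Missense Variants from Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting functional impairment of protein
    missense variants from molecular dynamics trajectories. Maps
    database-style missense records onto reference structures through
    isoform alignment, extracts active-site torsion angles and catalytic
    geometric parameters from multi-model trajectories, performs dihedral
    (sin/cos) principal component analysis, clusters trajectories by
    Bhattacharyya histogram overlap in the PC1-PC2 plane with UPGMA trees,
    derives binary affected/unaffected calls from tree branches relative
    to the wild type, and benchmarks calls against experimental
    classifications and sequence-based predictors with Cohen's kappa.
    Includes seeded synthetic-trajectory generators (von Mises torsions,
    Gaussian-mixture geometry) with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
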