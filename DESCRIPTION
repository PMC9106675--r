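Package: ppidrugg
Title: Structure-Based Druggability Assessment of Protein-Protein
    Interaction Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses the druggability of binding pockets on
    protein-protein interaction (PPI) interfaces from crystal structures.
    Computes ligand-seeded pocket descriptors (site points, enclosure,
    hydrophilicity) on a grid with deterministic ray casting, scores
    them with the SiteMap-style druggability equation
    Dscore = 0.094*sqrt(n) + 0.60*e - 0.324*p, and classifies targets
    under a four-class PPI scheme as well as Halgren's original scheme.
    Includes sequence alignment and Kabsch superposition for posing a
    reference ligand into apo or peptide-bound structures, drug-likeness
    auditing of inhibitor property tables (Lipinski rule of five, the
    relaxed one-violation variant, QED desirability scoring, and the
    Rule-of-Four profile of PPI inhibitors), a manifest-driven pipeline,
    and synthetic-structure generators that emulate cavities of
    controlled size, depth and polar lining for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
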