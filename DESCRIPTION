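Package: enzdesign
Title: Data-Driven Enzyme Redesign from Conservation, Co-Evolution and
    Structure
Version: 0.1.0
Authors@R:
    person("enzdesign", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for data-driven redesign of enzymes such as
    plant cytochrome P450s. Computes position-specific scoring matrices
    (PSSM) with sequence weighting from multiple sequence alignments, infers
    residue-residue co-evolution with a regularized pseudolikelihood Potts
    model and APC-corrected coupling scores, classifies residues by
    Shrake-Rupley solvent accessibility into surface / semi-exposed / buried
    and active-pocket classes, enumerates and clusters candidate variants
    with PAM30 distances, selects per-cluster representatives, composes
    beneficial substitutions with hyphenated variant nomenclature, and
    implements extracted-ion-chromatogram quantification with standard
    curves and product normalization. A synthetic-data module generates
    Potts-sampled alignments with planted couplings, toy helix structures
    and Gaussian-peak chromatograms so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
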