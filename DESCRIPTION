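Package: rfasite
Title: Mapping RFamide Neuropeptide Binding Sites on Acid-Sensing Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map the binding site of RFamide neuropeptides (such as
    FRRFa) on trimeric acid-sensing ion channels by combining rigid-receptor
    docking post-processing with electrophysiological modulation analysis.
    Reads receptor structures and docking pose ensembles (multi-MODEL PDB and
    AutoDock-style result files), selects cross-peptide consensus poses by
    RMSD over the shared Arg-Phe-amide moiety within an energy window, detects
    probe-accessible cavities and their volumes on a voxel grid, assigns poses
    to named pockets, applies an N-terminus orientation filter based on grid
    burial depth, and computes typed protein-peptide interaction fingerprints.
    A companion set of functions quantifies channel modulation from current
    traces: sustained/peak current ratios, steady-state desensitization Hill
    fits, concentration-response fits, association/dissociation kinetics, and
    wild-type versus mutant effect classification. Seeded synthetic-data
    generators emulate every input so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
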