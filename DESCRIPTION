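Package: contactensemble
Title: Consensus Residue-Residue Contact Prediction from Conformation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein residue-residue contacts by pooling contacts
    across an ensemble of 3D structural models (decoys). Contacts are defined
    on representative atoms (C-beta, C-alpha for glycine) at an 8 Angstrom
    threshold, counted across the ensemble, normalized to per-model
    frequencies, ranked, domain-filtered and truncated to top-L/5 predictions
    in CASP RR format. Includes evaluation against native structures
    (precision, recall, +/- delta neighborhood matching over medium and long
    sequence-separation ranges), quality-table-driven ensemble filtering,
    contact-satisfaction model ranking with GDT-TS selection loss, sequence
    clustering of predicted contacts with per-model cluster coverage, and a
    synthetic decoy-ensemble generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
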