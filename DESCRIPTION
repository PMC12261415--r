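Package: protacdeg
Title: E(3)-Equivariant Graph Learning for PROTAC Degradation Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts PROTAC-mediated target protein degradation from 3D
    structures of the PROTAC molecule, the protein-of-interest binding
    pocket, and the E3-ligase binding pocket. Builds attributed 3D molecule
    graphs from mol2/PDB/SMILES inputs, encodes them with an
    E(3)-equivariant graph neural network, pools node embeddings with a
    mutual attention mechanism keyed on selected chemical descriptors and
    Morgan fingerprints, and classifies degradation activity (high vs low
    by the DC50/Dmax rule). A memory-enhanced pseudolabeling loop enriches
    scarce activity labels from unlabeled entries. Includes a synthetic
    fixture generator so the full pipeline runs without external data,
    leakage-aware train/test splitting, ablation switches, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    bio3d,
    ChemmineR,
    ChemmineOB,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    withr
Config/testthat/edition: 3
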