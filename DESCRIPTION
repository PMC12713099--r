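Package: protactan
Title: Ternary Attention Networks for PROTAC Degradation Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a PROTAC (proteolysis targeting chimera) degrades
    its target protein by modeling the protein-of-interest (POI), the PROTAC
    molecule, and the E3 ligase jointly. Provides a hierarchical molecular-graph
    featurizer (per-atom descriptors concatenated with a molecule-level global
    feature of SMILES character codes and physicochemical properties), a
    pluggable protein sequence embedder with a learned linear adapter, a ternary
    attention network that scores every (POI substructure, PROTAC atom, E3
    substructure) triplet and fuses the three entities into a joint
    representation without adding fusion parameters, an edge-aware graph
    convolutional encoder, training and evaluation utilities, PROTAC-DB-style
    table curation with tiered DC50/Dmax labeling, leakage-safe dataset
    splitting by fingerprint and sequence similarity, attention-map
    interpretability exports, and a synthetic-data generator for offline
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
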