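Package: emcbind
Title: Prediction of EMC Chaperone Binding Affinity for Transmembrane Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the binding affinity of transmembrane
    domains (TMDs) to the ER membrane protein complex (EMC) chaperone site.
    Encodes TMD sequences with scaled amino-acid property indices
    (AAindex1 format), selects position-specific features by Pearson
    correlation against measured binding affinities, fits a single-hidden-
    layer neural-network regressor, and scores TMDs proteome-wide with
    exo/endo topology handling. Also provides a synthetic generator for
    ConMem-style substitution-scan binding datasets, and trajectory
    analysis utilities for helical TMDs: logistic residue-residue contact
    numbers and principal-axis tilt angles relative to the membrane normal.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
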