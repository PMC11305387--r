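Package: dockscreen
Title: Evaluation and Triage of Structure-Based Virtual Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking receptor models by ligand enrichment
    (ROC curves, adjusted semilogarithmic LogAUC, enrichment factors),
    selecting models from large ensembles, generating property-matched
    decoy sets, post-processing prospective docking screens (ensemble
    best-score ranking, PAINS and similarity filters, leader clustering),
    computing hit-rate and potency statistics for experimentally tested
    candidates, and symmetry-corrected structural comparison of binding
    sites. Includes a synthetic-data generator with known ground truth so
    the full pipeline can be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ChemmineOB,
    bio3d,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
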