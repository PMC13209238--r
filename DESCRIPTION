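Package: kindock
Title: Ensemble Docking Post-Processing and Kinase Isoform Selectivity
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for structure-based virtual screening
    against kinase conformational ensembles. Clusters binding-site
    conformations from crystallographic monomers by heavy-atom RMSD,
    selects cluster representatives (medoid plus max-min diversity picks)
    with a docking-fidelity replacement rule, evaluates per-conformer
    screening performance (ROC AUC, exponential ROC enrichment, enrichment
    factors, confusion-matrix metrics at top-ranked cutoffs), scores
    ligand selectivity between two kinase isoforms by the difference of
    normalized ranks, and computes geometric protein-ligand interaction
    fingerprints on canonical kinase binding-site positions, including
    hinge-motif detection and active/inactive bit enrichment. A synthetic
    data module generates conformer ensembles, dual-target score tables
    and toy complexes with known ground truth so that the entire pipeline
    is testable without external structure or bioactivity databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
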