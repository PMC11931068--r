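Package: dganet
Title: Drug-Adverse-Reaction Association Prediction from Pharmacogenomics Similarity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug - adverse drug reaction (ADR) associations by fusing
    five pharmacogenomics-derived similarity features: chemical-structure
    fingerprint Tanimoto similarity, cosine similarity of drug-perturbed
    expression signatures, Jaccard similarity of chemical-gene interaction
    sets, MeSH-style DAG semantic similarity of ADR terms, and Jaccard
    similarity of gene-disease association sets. Feature blocks are
    concatenated per entity, combined through a feature cross (outer
    product), and scored by a compact neural network (two linear subnetworks,
    a six-layer convolutional subnetwork over the cross, and a fully
    connected head) trained with the zero-anchored log-sum-exp pairwise rank
    (ZLPR) multi-label loss. Includes leakage-guarded class-balanced k-fold
    cross-validation with AUROC/AUPRC/accuracy/MCC reporting, optional
    association-profile neighbourhood features with held-out masking, readers
    for CTD/SIDER/MeSH-style tables, and a seedable synthetic-data generator
    with a planted drug-gene-ADR signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
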