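# dganet

Predicting drug–adverse-drug-reaction (ADR) associations from
pharmacogenomics similarity features.

Most ADRs are discovered late because structure-only screens ignore the
genomic route from drug to phenotype: drugs perturb genes, and gene–disease
links carry the perturbation to a clinical outcome. `dganet` is aimed at
computational pharmacology / drug-safety researchers who have access to
curated chemical–gene interaction (CGI) and gene–disease association (GDA)
tables, a MeSH-style ADR hierarchy, drug-perturbed expression signatures and
structural fingerprints, and want a reproducible pipeline that turns those
resources into ranked candidate drug–ADR pairs.

## The method

Five similarity views are computed, three for drugs and two for ADR terms:

| block | entities | measure |
|---|---|---|
| CS   | drugs | Tanimoto on binary fingerprints: x·y / (‖x‖² + ‖y‖² − x·y) |
| GE   | drugs | cosine on expression signatures |
| CGI  | drugs | Jaccard of interacting-gene sets: GT_i ∩ GT_j / GT_i ∪ GT_j |
| MESH | ADRs  | DAG semantic similarity with per-edge decay Δ = 0.5 |
| GDA  | ADRs  | Jaccard of associated-gene sets |

Per entity, the similarity rows are concatenated: Drug = (Sim_CS, Sim_GE,
Sim_CGI), Side = (Sim_MESH, Sim_GDA). A pair (d, s) is scored by a network
with two linear subnetworks (one per side), a six-layer convolutional
subnetwork over the feature cross V = Drug × Side (realized as the outer
product of linearly projected feature vectors), and a fully connected head;
scores above 0 are read as predicted associations. Training minimizes the
ZLPR multi-label rank loss

    L = log(e^{s0} + Σ_{i∈neg} e^{s_i}) + log(e^{−s0} + Σ_{j∈pos} e^{−s_j})

with Adam (learning rate 0.005). Evaluation is class-balanced 5-fold
cross-validation (AUROC, AUPRC, accuracy, MCC); optional association-profile
("DSA") neighbourhood features are rebuilt per fold with the held-out pairs
masked to zero, and the zero mask is asserted before training so the feature
can never leak test labels. A seedable synthetic generator with a planted
drug–gene–ADR signal exercises the whole pipeline without any downloads; see
the methods vignette (`vignettes/dganet-methods.Rmd`) for the model,
defaults, and what the synthetic benchmark does and does not demonstrate.

## Worked example

The built-in micro-dataset has every similarity hand-checkable:

```r
library(dganet)
we <- worked_example()           # 3 drugs, 3 ADR terms, 4 genes
fb <- build_feature_blocks(we)

fb$drug$cgi["d1", "d2"]   # 0.5      gene sets {g1,g2,g3} vs {g2,g3,g4}
fb$drug$cs["d1", "d2"]    # 0.3333   fingerprints [1,1,0] vs [1,0,1]
fb$drug$ge["d1", "d2"]    # 0.96     signatures [3,4] vs [4,3]
fb$adr$mesh["a1", "a2"]   # 0.3333   sibling terms under one root, Δ = 0.5
fb$adr$mesh["a1", "a3"]   # 0.6      child vs its root parent
fb$adr$gda["a1", "a2"]    # 0.25     gene sets {g1,g2} vs {g2,g3,g4}
```

A full run on the planted synthetic benchmark (30 drugs × 40 ADRs):

```r
ds <- generate_dataset(synthetic_config(seed = 1))
feats <- build_feature_blocks(ds)
report <- run_cross_validation(feats, ds$assoc,
                               drug_blocks = "cgi",
                               adr_blocks = c("mesh", "gda"),
                               k = 5, seed = 1, verbose = TRUE)
report[report$fold == "summary", c("auroc", "auprc", "acc", "mcc")]
#>       auroc     auprc       acc       mcc
#> 6 0.8793726 0.9028679 0.8367965 0.6793363
```

Mean test AUROC ≈ 0.88 against a Bayes-optimal ≈ 0.93 for this generator;
shuffling the labels (`shuffle_labels(ds, seed = 1)`) drops the same pipeline
to ≈ 0.46, confirming the score reflects the planted drug–gene–ADR mechanism
rather than structural artifacts.

The same pipeline is scriptable from a shell (the installed `exec/dganet`
launcher):

```sh
dganet simulate --out data/ --seed 1
dganet features --cgi data/cgi.tsv --gda data/gda.tsv --mesh data/mesh_tree.tsv \
                --ge data/ge_signatures.tsv --fps data/fingerprints.tsv --out feats/
dganet cv --features feats/ --assoc data/associations.tsv \
          --seed 1 --out report.tsv
```

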