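---
title: "Predicting drug–ADR associations from pharmacogenomics similarity features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug–ADR associations from pharmacogenomics similarity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most adverse drug reactions (ADRs) surface only after a drug is marketed, and
computational screens that rely on chemical structure alone miss the
pharmacogenomic route by which many reactions arise: a drug perturbs genes, and
gene–disease links carry that perturbation to a clinical phenotype. `dganet`
scores candidate (drug, ADR) pairs by fusing five similarity views of curated
pharmacogenomics resources:

* **CS** — Tanimoto similarity of binary structural fingerprints,
  $\mathrm{Sim}^{CS}_{ij} = \dfrac{x_i \cdot x_j}{\|x_i\|^2 + \|x_j\|^2 - x_i \cdot x_j}$;
* **GE** — cosine similarity of drug-perturbed expression signatures
  (consumed precomputed, e.g. landmark-gene signatures);
* **CGI** — Jaccard similarity of the gene sets each drug interacts with,
  $|GT_i \cap GT_j| / |GT_i \cup GT_j|$, built from a deduplicated
  chemical–gene interaction table;
* **MESH** — DAG semantic similarity of ADR terms in a MeSH-style hierarchy;
* **GDA** — Jaccard similarity of the gene sets associated with each ADR
  (disease term), from a deduplicated gene–disease association table.

A drug's feature vector is the concatenation of its rows across the drug-side
similarity matrices; an ADR's likewise across the ADR-side matrices. Interaction
direction, cell type, and evidence class are deliberately not weighted: a gene
either interacts with a drug (or associates with a disease) or it does not.
Identifiers are compared verbatim — gene symbols are case-meaningful.

## DAG semantic similarity

Each ADR term $s$ in the ontology defines an ancestor closure $N_s$. The
semantic contribution of a node $n$ decays with distance from $s$:

$$C_s(s) = 1, \qquad
  C_s(n) = \max\{\Delta \cdot C_s(n') : n' \text{ child of } n\},$$

with contribution factor $\Delta = 0.5$ by default. The semantic value is
$DV(s) = \sum_{n \in N_s} C_s(n)$ and the similarity of two terms is

$$\mathrm{Sim}(s_i, s_j) =
  \frac{\sum_{n \in N_{s_i} \cap N_{s_j}} \left(C_{s_i}(n) + C_{s_j}(n)\right)}
       {DV(s_i) + DV(s_j)}.$$

Descriptors holding several tree addresses (the classic example is a term like
Angioedema that sits under cardiovascular, skin, and immune-system categories
simultaneously) merge into a single node before closure computation; the
max-over-children recursion then takes the best path automatically. The closure
is computed by dynamic programming over the parent relation and is checked in
the test suite against exhaustive path enumeration.

Two properties are worth noting. Adding a shared ancestor never decreases the
similarity of two terms. However, similarity is **not** globally monotone in
$\Delta$: a term with deep *private* ancestry has $DV$ growing faster in
$\Delta$ than the shared-ancestor sum, so its off-diagonal similarities can
fall as $\Delta$ rises. The test suite asserts monotonicity only on
shared-chain sibling structures, where the closed form $S/(1+S)$ (with $S$ the
chain decay sum) makes it provable.

ADR terms missing from the ontology are an error by default (`strict = TRUE`),
because unmappable terms should be excluded during data assembly; lenient mode
treats them as isolated nodes.

## The model

For a pair $(d, s)$ the network combines three branches:

1. **Linear subnetworks (LSN)**, one per side:
   `Linear(Dropout(ReLU(FC(x))))` with hidden width `lsn_hidden` (default 256)
   and embedding width `emb_dim` (default 64).
2. **A feature cross** $V = (P_d^\top x_d)(P_s^\top x_s)^\top$, the outer
   product of linearly projected feature vectors. The projections $P_d, P_s$
   are trained with the model; their dimensions bound the cross fed to the
   convolutional branch. `NULL` feeds the raw outer product.
3. **A convolutional subnetwork (CSN)** of six layers — three stages of
   3×3 convolution (8/16/32 channels, ReLU) each followed by 2×2 max pooling —
   whose flattened output embeds the cross. A 64×64 cross reduces to
   8×8×32 before flattening.

The embeddings are concatenated and passed through a fully connected head
(hidden width `head_hidden`, default 128, ReLU + dropout, then a linear unit).
Scores above the anchor $s_0 = 0$ are read as predicted associations. The head
optionally applies a final ReLU to match the published formulation; the default
is the identity because a ReLU head clips all negative evidence to zero —
every rejected pair collapses to score exactly 0, which destroys ranking below
the threshold — so ranking metrics always use pre-threshold scores.

Training minimizes the ZLPR (zero-anchored log-sum-exp pairwise rank)
multi-label loss

$$L = \log\Big(e^{s_0} + \sum_{i \in \Omega_{neg}} e^{s_i}\Big)
    + \log\Big(e^{-s_0} + \sum_{j \in \Omega_{pos}} e^{-s_j}\Big),$$

computed with log-sum-exp stabilization (finite up to scores of $\pm 10^4$ and
beyond). Within a mini-batch the pairs of one drug form one loss group
($\Omega_{pos}/\Omega_{neg}$ = that drug's positive/negative ADRs in the
batch): ZLPR is a set-wise loss and grouping drug-wise matches the multi-label
reading of the task. The optimizer is Adam at learning rate 0.005 with no
schedule. All forward/backward passes are hand-derived base-R linear algebra
(im2col convolutions through BLAS); the test suite validates every parameter
group against numerical differentiation, which is the strongest available
oracle for a from-scratch network.

### Defaults and their rationale

| parameter | default | note |
|---|---|---|
| `lsn_hidden` / `head_hidden` | 256 / 128 | capacity matched to feature widths in the hundreds |
| `emb_dim` | 64 | per-branch embedding |
| `dropout` | 0.3 | standard regularization for small tabular-ish data |
| `conv_channels` | 8, 16, 32 | six-layer CSN: 3 × (conv 3×3 + maxpool 2×2) |
| `proj_d`, `proj_s` | 16 | see below |
| `learning_rate` | 0.005 | published setting |
| `s0` | 0 | anchor; also the classification threshold |
| `epochs` / `batch_size` | 50 / 128 | small-data schedule |

At production scale (hundreds of drugs, feature widths in the thousands) a raw
cross is memory-hostile and a 64×64 projection is the recommended setting. The
package default of 16×16 is sized to the desk-scale feature widths (tens of
columns) used in the examples, simulations and tests: a 64×64 cross built from
30–80-dimensional inputs adds no information over 16×16, only computation.
Both are configuration, not architecture.

## Evaluation protocol

Known positives are split into $k = 5$ folds. Per fold the model trains on the
other folds' positives plus an equal number of uniformly sampled negative
pairs (never colliding with any known positive) and is tested on the held-out
positives plus a matching, disjoint negative sample — test sets are
class-balanced too, which keeps AUROC and AUPRC on comparable scales. Metrics:
AUROC by the rank (Mann–Whitney) estimator with average ranks on ties; AUPRC
by non-interpolated step integration; accuracy and Matthews correlation at
`score > 0`, with MCC defined as 0 whenever a confusion-matrix margin is zero.
Whether test negatives should be resampled per fold or fixed once is a
protocol choice; they are resampled per fold here, controlled by one root seed
that derives per-stage seeds, so a report is a pure function of (data, config,
seed).

The optional neighbourhood feature (DSA blocks) builds the binary drug × ADR
association matrix and takes Jaccard similarity of row (drug) or column (ADR)
profiles. Because this feature is constructed from the labels themselves, each
fold rebuilds it with the fold's held-out pairs forced to zero, and the runner
*asserts* (not assumes) that every held-out position is zero before training —
an injected violation aborts the fold. The profile-similarity definition is
Jaccard; neighbourhood features of this kind vary across the literature, so the
choice is isolated behind one function.

## The synthetic benchmark

The generator emulates the full data ecosystem: a rooted ontology DAG with
multi-address nodes (each new node attaches to an existing one, with a second
parent with probability 0.2), per-drug and per-ADR gene sets, an expression
matrix, fingerprints, and an association table, all reproducible byte-for-byte
from one seed.

The planted mechanism links labels to gene-set overlap — exactly the structure
the CGI/GDA features can expose. Genes are organized into latent pathway
modules (default: 8 modules of 25 genes in a 200-gene universe); each drug and
ADR draws `module_frac` (default 0.95) of its gene set from a home module and
the rest from the background, and

$$P(\text{assoc}) = \min\!\big(1,\; \pi_0 + \beta \cdot
  \mathrm{Jaccard}(GT_d, GS_a)\big),$$

with labels drawn Bernoulli. The module structure mirrors how curated
chemical–gene and disease–gene sets cluster into pathways; without it
(independent uniform gene sets of this size) the overlap distribution is so
concentrated that even the Bayes-optimal scorer barely exceeds AUROC 0.6, and
no pipeline could demonstrate signal recovery. Under the defaults same-module
pairs overlap at Jaccard ≈ 0.7 (association probability ≈ 0.6), cross-module
pairs at ≈ 0, the positive density lands near 5–10% (comparable to real
drug-label matrices), and the Bayes-optimal AUROC of the planted model is
about 0.93 — so a working pipeline has headroom to clear 0.8 and a broken one
shows a visible shortfall. $\pi_0$ (default 0.01) is the background rate of
associations with no shared-gene mechanism; it is the irreducible noise floor
of the benchmark. Expression signatures are a fixed random projection of the
gene-set indicator plus Gaussian noise ($\sigma = 0.3$); fingerprints are
random bits with crossover copying between gene-sharing drugs; ontology leaves
are assigned so gene-sharing ADRs sit near each other with probability
$\beta$. An optional long-tail mode multiplies per-drug association
probabilities by Zipf-like exposure weights, reproducing the frequency–rank
skew of real association tables.

What passing the synthetic tests does **not** show: the generator's similarity
blocks are cleaner and lower-dimensional than real CTD/SIDER-scale data, its
label noise is exactly Bernoulli, and its gene sets lack the extreme
long-tailed set-size variation of curated databases. Results on it validate
the machinery (features, leakage guards, optimization, metrics), not clinical
performance.

The no-signal control in the acceptance suite uses $\beta = 0$ with $\pi_0$
raised to the planted condition's positive density (0.09), so the signal and
control runs differ only in the planted mechanism, not in class sizes. At the
default $\pi_0 = 0.01$ a $\beta = 0$ dataset has only a dozen positives and a
5-fold AUROC estimate would be dominated by sampling noise.

Desk-scale problem sizes used throughout the tests and the acceptance script —
30 drugs × 40 ADRs, 5 folds, the model configuration above — were chosen as
the smallest sizes at which fold metrics are stable enough to interpret;
everything scales with configuration.

## Numerical and degenerate-input conventions

* Entities with no feature signal (empty gene set, all-zero fingerprint,
  zero-norm signature): similarity 0 to everything, 1 to themselves, with a
  warning; strict modes error instead. This keeps matrices well-defined
  without silently dropping entities — exclusion is a data-assembly decision,
  not a similarity-operator side effect.
* Orphan tree addresses attach to a synthetic per-category root (warning);
  cycles in the address table are an error.
* Max pooling uses ceiling semantics (odd extents padded with $-\infty$), so
  any cross of at least 4×4 flows through the three pooling stages.
* Ties in AUROC take average ranks; AUPRC is non-interpolated; tied score
  blocks are evaluated at block ends (this matches the standard
  average-precision estimator exactly).
* MCC with any zero denominator is 0; single-class test sets report NaN
  ranking metrics with a warning rather than failing the run.
* All randomness (initialization, dropout, batch order, sampling) flows from
  explicit seeds through a save/restore RNG scope, so library calls never
  perturb the caller's RNG state.

## Known limitations

* Expression signatures are consumed as given; computing them from raw
  perturbation data is out of scope.
* Cross-vocabulary identifier mapping (MedDRA/UMLS/OMOP chains) is out of
  scope; inputs must already share identifier spaces, or be joined through a
  synonym table upstream.
* The from-scratch network is single-threaded CPU linear algebra: adequate for
  the desk scale it targets, not for thousands of entities per side without a
  larger projection budget and patience.
* Fold splitting is over positive pairs, matching the standard protocol for
  this task; drugs seen in training can appear in test pairs. Cold-start
  (drug-held-out) evaluation is a different protocol and is not implemented.
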