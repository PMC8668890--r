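---
title: "Methods: network-guided biomarker selection in gnnsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-guided biomarker selection in gnnsc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gnnsc)
```

## Overview and model

`gnnsc` selects a biomarker panel of size `mu` from a two-class expression
matrix by letting a prior-knowledge gene interaction graph decide which
genes are redundant with one another. The working assumption is the usual
one in network biology: genes whose products interact physically tend to
share function and co-express, so interacting neighborhoods carry largely
interchangeable phenotype information. The pipeline therefore groups genes
by network-informed similarity first and only then asks, within each group,
which single gene carries the most label information.

The stages, and the modeling choices inside each, are described below.

## Graph construction

Nodes are the dataset's genes, sorted lexicographically so all matrices are
reproducible. Edges come from a weighted interaction list restricted to
genes present in the data; duplicate records keep the maximum weight
(conservative toward stronger evidence) and self-loops are dropped. Genes
without any interaction are kept as isolated nodes by default
(`keep_isolated = TRUE`): dropping them would silently shrink the feature
space, while keeping them costs nothing — their neighborhood aggregate is
defined as the zero vector, so they flow through clustering and selection
on the strength of their own expression profile.

Each node's initial state is its expression profile across samples,
z-scored per gene by default (`scale_states = TRUE`). Both the cosine
similarity used in link prediction and the Gaussian kernel used in
clustering are scale-sensitive; without standardization, high-intensity
genes would dominate every distance regardless of information content.

## Layered neighborhood aggregation

One layer updates every node synchronously:

* aggregate: `a_v = sum_u (w_vu / sum_u' w_vu') h_u` — an edge-weighted
  *mean* of neighbor states. Normalizing the edge weights within each
  neighborhood keeps state magnitudes layer-stable and makes hub degree
  irrelevant to scale.
* update: `h_v <- sigma(W %*% c(h_v, a_v))`, then L2 normalization.
  A pre-activation vector that is exactly zero (possible for isolated
  all-zero nodes, or under ReLU) is passed through unchanged rather than
  normalized, avoiding NaNs.

Synchronous (Jacobi-style) updates are used rather than in-place sweeps:
in-place updates would make the result depend on node order. The activation
defaults to ReLU (standard for this family of aggregation networks;
sigmoid/tanh/identity are available), weight matrices are Glorot-uniform
initialized from the run seed, and the defaults are `layers = 10` and
`hidden_dim = 32`. Ten layers is deliberately deep for graphs of this size —
states mix across whole modules, which is precisely what makes module
members near-interchangeable downstream. The edge-weighting step is
non-learned weight normalization; a learned attention variant was
considered and rejected as underdetermined by the small sample sizes this
tool targets.

## Link prediction

Existing edges are positives. For each positive edge, `gamma = 5`
non-neighbor partners are drawn for each endpoint (excluding self and all
existing edges), giving up to `2*gamma` negatives owned by that positive.
Pair scores are cosine similarities of the final embeddings, and the loss
is the standard negative-sampling objective: `-log sigma(sim)` for
positives, `-log sigma(-sim)` for negatives, averaged over positives. Note
the sign flip on negatives — the objective must *reward* low negative-pair
similarity for minimization to separate edges from non-edges.

Training is full-batch gradient descent (`lr = 0.01`) through the
propagation layers, implemented by reverse-mode differentiation of the
aggregate/update/normalize chain; graphs at this scale do not need
minibatching. Iteration stops when the loss changes by less than
`delta = 1e-4` between adjacent epochs, capped at `max_epochs = 200`.
Model selection is by mean reciprocal rank: each evaluation positive
(held-out edges when available, otherwise a 20% validation split of the
positives) is ranked against its negatives, and the epoch with the highest
MRR supplies the final parameters. Ranking uses competition ranks with the
positive winning exact ties.

Augmentation scores non-adjacent pairs by the confidence
`sigma(cosine similarity)` and adds an edge (weighted by that confidence,
keeping all weights positive) when it reaches `theta`. Two bounded-design
choices matter here:

* Since cosine similarity is at most 1, confidences never exceed
  `sigma(1) ~ 0.731`. The default threshold is therefore `theta = 0.70`
  (cosine ~ 0.85), high enough to admit only near-parallel embeddings but
  attainable; `theta = 1` is the exact no-augmentation ablation arm.
* The default candidate scope is `two_hop`: only non-adjacent pairs sharing
  a neighbor are scored. All-pairs scoring is quadratic in gene count and
  adds edges between modules that merely look alike in expression;
  restricting to two hops keeps augmentation local to existing network
  structure. `all_pairs` is available behind a flag.

## Spectral clustering

Embeddings are *recomputed* on the augmented graph `G*` with the trained
parameters before clustering. This is the only ordering in which link
prediction can influence clustering through both the edge set (changed
aggregation neighborhoods) and the node states; clustering the
pre-augmentation embeddings would reduce augmentation to a no-op.

The Gaussian kernel is evaluated densely on all node pairs, with bandwidth
`Omega = "auto"` set to the median pairwise embedding distance — a standard
heuristic that keeps the kernel responsive across seeds without tuning.
The symmetric normalized Laplacian's `mu` smallest eigenvectors form the
spectral embedding; eigenvector signs are fixed (largest-magnitude entry
positive) for solver-independent determinism, and rows are unit-normalized
by default, the usual companion step for this Laplacian. k-means uses
k-means++ seeding, best of `restarts = 10` runs by within-cluster sum of
squares, with empty clusters repaired by splitting the largest cluster at
its farthest point. `mu` is a user input equal to the output panel size;
no automatic eigengap selection is attempted.

## Per-cluster scoring and selection

The default scorer fits one ordinary least squares model of the labels on
the cluster's standardized genes *jointly*, scoring each gene by
`|coefficient|`. Clusters exist to group redundant genes, and a joint fit
lets that redundancy suppress duplicate weight — two near-copies split
their coefficient rather than both ranking high. When the joint fit is
singular (more genes than samples, exact collinearity) the scorer falls
back to ridge regression with a small fixed penalty and logs the fact.
Per-gene fits are available via `scorer_params = list(joint = FALSE)`.
Alternative scorers (`logistic`, `corr`, `rf_importance`, `rfe_rank`)
plug into the same surface, both for use inside clusters and as whole-gene
baselines in comparisons. Argmax ties are real on small data; they are
broken by higher gene variance, then lexicographic ID, so runs are
deterministic.

## Evaluation

Panels are scored by stratified k-fold (default 5) cross-validation of a
linear-kernel SVM with `C = 1` on features standardized within each
training fold. Sensitivity is recall of class 1, specificity recall of
class 0, and AUC uses the continuous decision values under the
Mann-Whitney tie convention (ties count 1/2). The fold assignment is
computed once per dataset seed and shared across all arms of a comparison,
so pipeline-vs-baseline contrasts are paired. The linear kernel is the
transparent default — with panels of 1-15 genes and tens of samples an RBF
kernel mostly adds variance — and is swappable (`svm_rbf`).

Group-difference reporting uses the Wilcoxon rank-sum test: exact when
both groups have at most 12 samples and no ties, otherwise the
tie-corrected normal approximation without continuity correction. Star
codes are `*` p<0.05, `**` p<0.01, `****` p<0.0001 (no `***` tier is
defined, matching the reporting convention this follows).

## The synthetic-study generator

`generate_synthetic_study()` emulates the regime the method is built for:
60 samples (balanced classes), 200 genes partitioned into 5 modules of 40
(any remainder would form an unstructured background pool), 4 informative
genes per module with a between-class mean shift of 1.5 noise-SD units,
intra-module edge probability 0.3, inter-module 0.01, edge weights
Uniform(0.5, 1) so the edge-weight coefficient in aggregation is genuinely
exercised.

Genes within a module additionally share a latent Gaussian factor scaled
so the within-module expression correlation is `module_cor = 0.3`. This
co-expression term is essential, not decorative: without it every gene's
noise is independent, redundancy does not exist, and any comparison
between the pipeline and a marginal-correlation baseline is vacuous.
Correlated modules are also what the interaction-graph premise predicts
for physically interacting genes. What the generator does **not** emulate:
probe effects, batch effects, heavy-tailed intensity distributions,
class-dependent covariance, or any relationship between edge weight and
co-expression strength. Tests passing on this generator show the machinery
is correct and the method's comparative claims hold under its own
assumptions — not that those claims transfer to any particular clinical
dataset.

## Numerical and determinism notes

* All randomness flows from explicit integer seeds; stage seeds are
  derived from the global seed with fixed offsets, kept below 2^31.
* Zero-norm vectors: cosine similarity with a zero vector is defined as 0,
  zero rows pass through L2 normalization unchanged, and constant genes
  get correlation score 0 rather than NaN.
* Eigen-decompositions use the symmetric solver; eigenvalues of the
  normalized Laplacian are clamped only by test tolerance (1e-8), never in
  code.
* Held-out edge splits refuse to isolate a node while non-isolating
  candidates remain, so link-prediction evaluation graphs stay connected
  where possible.
* Problem sizes used in the test-suite: studies of 200 genes x 60
  samples, 10-20 Monte-Carlo seeds per distributional claim, chosen to
  make each claim decidable in minutes on one core.

## Known limitations

* Binary labels only; multi-class designs are out of scope.
* One interaction channel: a single weighted relation (e.g. physical
  interaction); multiple evidence channels are not modeled.
* The link-prediction decoder is similarity-only; bilinear or MLP scorers
  are deliberately excluded.
* `mu` must be supplied by the user; the package does not choose the panel
  size.
* Expression input must be pre-exported to delimited text; platform
  annotation (probe-to-gene) mapping is file-driven, not queried from any
  service.
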