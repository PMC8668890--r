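# gnnsc

Network-guided biomarker selection from two-class expression data, combining
graph neural embeddings, link prediction, and spectral clustering.

## The problem

Microarray and other bulk expression studies have few samples and thousands
of correlated genes. Marginal feature selectors (correlation filters,
per-gene tests) rank redundant co-expressed genes together and waste panel
slots, and they ignore what is already known about which gene products
physically interact. `gnnsc` is for analysts who want a compact biomarker
panel that (a) uses a prior-knowledge gene interaction network and (b)
spends each panel slot on a different co-expression module.

## The method

Given a samples × genes matrix `X` with binary labels `y` and a weighted
gene–gene interaction list (e.g. physical interactions exported from
GeneMANIA):

1. **Gene graph.** Build `G = (V, E)` with one node per gene; node `v`'s
   initial state is its (z-scored) expression profile, `h⁰_v ∈ ℝⁿ`.
2. **Layered propagation.** For `K = 1..L` (default `L = 10`), every node
   aggregates its neighborhood as an edge-weighted mean,
   `a_v = Σ_u (w_vu / Σ_{u'} w_vu') h^{K-1}_u`, then updates
   `h^K_v = σ(W^K · [h^{K-1}_v ; a_v])` followed by L2 normalization
   (GraphSAGE-style mean aggregation with edge weighting).
3. **Link prediction.** Graph edges are positives; `γ` sampled non-neighbors
   per endpoint are negatives. The layer weights `W^K` are trained by
   gradient descent on the negative-sampling loss
   `L = E_pos[ −log σ(sim(v_j, v_r)) − Σ_neg log σ(−sim(v̄_j, v̄_r)) ]`
   with `sim` the cosine similarity of final embeddings; the epoch with the
   best mean reciprocal rank (MRR) of positives among their negatives is
   kept. Non-adjacent pairs with confidence `σ(sim) ≥ θ` become new edges,
   giving the augmented graph `G*`.
4. **Spectral clustering.** Embeddings are recomputed on `G*`, turned into a
   Gaussian kernel `w_ab = exp(−‖e_a − e_b‖² / 2Ω²)`, and the `μ` smallest
   eigenvectors of the normalized Laplacian `L = D^{−1/2}(D − W)D^{−1/2}`
   are clustered by k-means, partitioning the genes into `μ` subgraphs.
5. **Biomarker selection.** Within each cluster an embedded scorer (default:
   joint linear model on standardized genes; logistic / correlation /
   random forest / SVM-RFE also available) weights the genes; the
   top-weighted gene of each cluster is a biomarker, so `μ` is the panel
   size. Panels are evaluated by stratified 5-fold cross-validated SVM
   (accuracy, sensitivity, specificity, AUC).

A synthetic-study generator plants informative genes inside co-expressed,
densely connected network modules so the whole pipeline is testable without
any external downloads.

## Worked example

```r
library(gnnsc)

study <- generate_synthetic_study(seed = 7)   # 60 samples x 200 genes,
                                              # 5 modules, 20 informative genes
res <- run_pipeline(study$dataset, study$edges, pipeline_config(seed = 7))
#> graph: 200 nodes, 1288 edges
#> link model: best MRR 0.9144 at epoch 146 (150 epochs run)
#> augment_graph: added 1605 predicted edge(s)
#> G*: 2893 edges (was 1288)
#> partition_graph: dropped 226 cross-cluster edge(s)
#> score_subcluster: singular joint linear fit (73 genes, 60 samples); ridge fallback
#> selected biomarkers: g0135, g0048, g0176, g0111, g0086
#> CV means: acc 0.8333 sens 0.8667 spec 0.8000 auc 0.9611

res$ranking$selected
#> [1] "g0135" "g0048" "g0176" "g0111" "g0086"
sum(res$ranking$selected %in% study$truth$informative_genes)
#> [1] 3
biomarker_report(study$dataset, res$ranking$selected)
```

The five selected genes are one per spectral cluster; three of them are
planted informative genes (a random 5-gene panel would contain 0.5 on
average). The CV line is the stratified 5-fold SVM evaluation of that
panel; `biomarker_report` adds per-gene group means and Wilcoxon rank-sum
p-values. Real data enter the same way through `read_expression_matrix()`,
`read_edge_list()`, and optionally `apply_probe_map()`; a thin CLI wrapper
(`inst/cli/gnnsc`) exposes `simulate`, `run`, `compare`, and `report`
subcommands.

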