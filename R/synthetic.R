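#' Generate a synthetic two-class expression study with a matching gene graph
#'
#' Emulates the structure the pipeline is designed for: genes organized into
#' network modules of interacting, co-expressed genes, a subset of which are
#' informative for the (binary) phenotype. Genes are partitioned into
#' `n_modules` equal blocks of `n_genes %/% n_modules` genes; any remainder
#' forms an unstructured background pool. Expression of gene j in sample i is
#'
#'   x_ij = shift_j(y_i) + b * f_{m(j),i} + e_ij
#'
#' with e_ij ~ N(0, noise_sd^2) i.i.d., f_{m,i} ~ N(0,1) a latent factor
#' shared by all genes of module m (background genes have none), and
#' b = noise_sd * sqrt(module_cor / (1 - module_cor)) so that `module_cor`
#' is the within-module expression correlation. `informative_per_module`
#' genes per module additionally receive a class-conditional mean shift of
#' +/- effect_size * noise_sd / 2, i.e. a between-class mean difference of
#' `effect_size` in units of the independent noise SD. Graph edges are drawn
#' independently: probability `intra_module_edge_prob` within a module,
#' `inter_module_edge_prob` otherwise, weights ~ Uniform(0.5, 1).
#'
#' @param n_samples,n_genes study dimensions (classes balanced to within one
#'   sample).
#' @param n_modules number of gene modules.
#' @param informative_per_module informative genes planted per module.
#' @param effect_size between-class mean shift, in noise-SD units.
#' @param intra_module_edge_prob,inter_module_edge_prob edge probabilities.
#' @param noise_sd SD of the i.i.d. expression noise.
#' @param module_cor within-module expression correlation in `[0, 1)`
#'   contributed by the shared module factor; 0 disables co-expression.
#' @param seed integer seed; the same seed reproduces identical outputs.
#' @return list with `dataset` ([expression_dataset()]), `edges`
#'   ([weighted_edge_list()]), and `truth` (class `synthetic_truth`: elements
#'   `informative_genes`, `module_membership` — named integer, 0 =
#'   background —, `heldout_edges` (NULL until [holdout_edges()] is used),
#'   `effect_size`, `seed`).
#' @export
generate_synthetic_study <- function(n_samples = 60, n_genes = 200,
                                     n_modules = 5, informative_per_module = 4,
                                     effect_size = 1.5,
                                     intra_module_edge_prob = 0.3,
                                     inter_module_edge_prob = 0.01,
                                     noise_sd = 1.0, module_cor = 0.3,
                                     seed = 1) {
  if (n_modules < 1 || informative_per_module < 0)
    stop("parameter error: n_modules >= 1 and informative_per_module >= 0 required")
  if (n_modules * informative_per_module > n_genes)
    stop("parameter error: n_modules * informative_per_module exceeds n_genes")
  module_size <- n_genes %/% n_modules
  if (informative_per_module > module_size)
    stop("parameter error: informative_per_module exceeds module size ", module_size)
  if (intra_module_edge_prob <= 0 || intra_module_edge_prob > 1 ||
      inter_module_edge_prob < 0 || inter_module_edge_prob >= 1)
    stop("parameter error: edge probabilities out of range")
  if (noise_sd <= 0) stop("parameter error: noise_sd must be positive")
  if (module_cor < 0 || module_cor >= 1)
    stop("parameter error: module_cor must be in [0, 1)")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  membership <- integer(n_genes)  # 0 = background
  for (m in seq_len(n_modules))
    membership[((m - 1L) * module_size + 1L):(m * module_size)] <- m
  names(membership) <- gene_ids

  n1 <- n_samples %/% 2L
  y <- c(rep(0L, n_samples - n1), rep(1L, n1))

  with_seed(seed, {
    informative <- unlist(lapply(seq_len(n_modules), function(m) {
      sort(sample(gene_ids[membership == m], informative_per_module))
    }))
    b <- noise_sd * sqrt(module_cor / (1 - module_cor))
    fac <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
    X <- matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd),
                n_samples, n_genes, dimnames = list(sample_ids, gene_ids))
    for (j in seq_len(n_genes)) {
      m <- membership[j]
      if (m > 0L && b > 0) X[, j] <- X[, j] + b * fac[, m]
    }
    shift <- effect_size * noise_sd / 2
    X[, informative] <- X[, informative] + ifelse(y == 1L, shift, -shift)

    # independent Bernoulli edges; iterate unordered pairs in canonical order
    pairs <- utils::combn(n_genes, 2L)
    same <- membership[pairs[1L, ]] == membership[pairs[2L, ]] &
      membership[pairs[1L, ]] > 0L
    p_edge <- ifelse(same, intra_module_edge_prob, inter_module_edge_prob)
    draw <- stats::runif(ncol(pairs)) < p_edge
    ea <- gene_ids[pairs[1L, draw]]
    eb <- gene_ids[pairs[2L, draw]]
    ew <- stats::runif(sum(draw), 0.5, 1.0)
    edges <- weighted_edge_list(ea, eb, ew)
  })

  truth <- structure(list(informative_genes = informative,
                          module_membership = membership,
                          heldout_edges = NULL,
                          effect_size = effect_size,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(dataset = expression_dataset(X, y), edges = edges, truth = truth)
}

#' Split an edge list into training and held-out sets
#'
#' Holds out `round(fraction * nrow(edges))` edges for link-prediction
#' evaluation. Candidates whose removal would isolate an endpoint are skipped
#' while alternatives remain; if the quota cannot be met otherwise, isolating
#' removals are used and logged.
#'
#' @param edges a [weighted_edge_list()].
#' @param fraction fraction of edges to hold out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `heldout`, both [weighted_edge_list()]s,
#'   disjoint with union equal to `edges`.
#' @export
holdout_edges <- function(edges, fraction, seed = 1) {
  if (!nrow(edges)) stop("parameter error: empty edge list")
  if (fraction <= 0 || fraction >= 1) stop("parameter error: fraction must be in (0, 1)")
  n_hold <- round(fraction * nrow(edges))
  if (n_hold < 1L) stop("parameter error: fraction holds out zero edges")
  if (nrow(edges) - n_hold < 1L) stop("parameter error: no training edges would remain")

  deg <- table(c(edges$gene_a, edges$gene_b))
  degree <- stats::setNames(as.integer(deg), names(deg))
  ord <- with_seed(seed, sample.int(nrow(edges)))
  held <- logical(nrow(edges))
  n_taken <- 0L
  for (i in ord) {
    if (n_taken == n_hold) break
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (degree[a] > 1L && degree[b] > 1L) {
      held[i] <- TRUE
      degree[a] <- degree[a] - 1L
      degree[b] <- degree[b] - 1L
      n_taken <- n_taken + 1L
    }
  }
  if (n_taken < n_hold) {
    # only isolating candidates remain: take them anyway
    for (i in ord) {
      if (n_taken == n_hold) break
      if (!held[i]) { held[i] <- TRUE; n_taken <- n_taken + 1L }
    }
    gnnsc_log("holdout_edges: %d removal(s) isolate a node (no alternative)", n_taken)
  }
  train <- edges[!held, , drop = FALSE]
  heldout <- edges[held, , drop = FALSE]
  rownames(train) <- NULL; rownames(heldout) <- NULL
  class(train) <- class(heldout) <- c("weighted_edge_list", "data.frame")
  list(train = train, heldout = heldout)
}
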