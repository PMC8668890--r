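#' Build positive and negative link samples
#'
#' Every edge of the graph is a positive sample. For each positive edge
#' (v_j, v_r), `gamma` partners are drawn uniformly without replacement for
#' each endpoint from its non-neighbors (excluding self and all existing
#' edges), and the resulting pairs are that positive's negatives — up to
#' `2 * gamma` of them, fewer when an endpoint has too few non-neighbors
#' (logged, not fatal).
#'
#' @param g a `gene_graph` with at least one edge and three nodes.
#' @param gamma negatives per endpoint per positive (>= 1).
#' @param seed integer seed; the same seed reproduces the sample sets.
#' @return A `link_sample_set`: list with `pos` (k x 2 integer matrix of
#'   node indices), `neg` (length-k list of n_i x 2 matrices, grouped by the
#'   positive that spawned them), `gamma`, `seed`, `nodes` (ID vector the
#'   indices refer to).
#' @export
build_link_samples <- function(g, gamma = 5, seed = 1) {
  if (gamma < 1) stop("gamma must be >= 1")
  m <- length(g$nodes)
  if (m < 3L) stop("graph must have at least 3 nodes")
  pos <- graph_edge_indices(g)
  if (!nrow(pos)) stop("graph has no edges")
  nbr <- graph_neighbors(g)
  short <- 0L
  neg <- with_seed(seed, lapply(seq_len(nrow(pos)), function(k) {
    out <- lapply(pos[k, ], function(v) {
      cand <- setdiff(seq_len(m), c(v, nbr[[v]]))
      take <- min(gamma, length(cand))
      if (take < 1L) return(matrix(integer(), 0L, 2L))
      partners <- if (length(cand) == 1L) cand else sample(cand, take)
      cbind(rep.int(v, take), partners)
    })
    nm <- do.call(rbind, out)
    if (nrow(nm) < 2L * gamma) short <<- short + 1L
    nm
  }))
  if (short > 0L)
    gnnsc_log("build_link_samples: %d positive(s) own fewer than 2*gamma negatives", short)
  structure(list(pos = pos, neg = neg, gamma = as.integer(gamma),
                 seed = as.integer(seed), nodes = g$nodes),
            class = "link_sample_set")
}

#' Cosine similarity between two embedding vectors
#'
#' `(a . b) / (||a|| ||b||)`, in `[-1, 1]`; defined as 0 when either vector
#' is all zeros.
#'
#' @param z_a,z_b numeric vectors of equal dimension.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(z_a, z_b) {
  if (length(z_a) != length(z_b))
    stop("shape error: vectors have dimensions ", length(z_a), " and ", length(z_b))
  na <- sqrt(sum(z_a^2)); nb <- sqrt(sum(z_b^2))
  if (na == 0 || nb == 0) return(0)
  sum(z_a * z_b) / (na * nb)
}

# Cosine similarities for index pairs (rows of `pairs`) over embedding
# matrix H; zero rows yield similarity 0.
pair_similarities <- function(H, pairs) {
  nrm <- row_norms(H)
  ha <- H[pairs[, 1L], , drop = FALSE]
  hb <- H[pairs[, 2L], , drop = FALSE]
  denom <- nrm[pairs[, 1L]] * nrm[pairs[, 2L]]
  s <- rowSums(ha * hb)
  ifelse(denom > 0, s / denom, 0)
}

#' Negative-sampling link loss
#'
#' Mean over positive edges of
#' `-log sigma(sim(pos)) - sum_neg log sigma(-sim(neg))` with `sigma` the
#' logistic function and `sim` cosine similarity of the endpoint embeddings:
#' low loss means positives score high and sampled non-edges score low.
#'
#' @param samples a [build_link_samples()] result.
#' @param emb node embedding matrix (rows follow `samples$nodes`).
#' @return positive finite scalar loss.
#' @export
link_loss <- function(samples, emb) {
  if (!nrow(samples$pos)) stop("value error: empty positive sample set")
  s_pos <- pair_similarities(emb, samples$pos)
  total <- sum(-log(logistic(s_pos)))
  neg_all <- do.call(rbind, samples$neg)
  if (!is.null(neg_all) && nrow(neg_all)) {
    s_neg <- pair_similarities(emb, neg_all)
    total <- total + sum(-log(logistic(-s_neg)))
  }
  total / nrow(samples$pos)
}

#' Mean reciprocal rank
#'
#' `MRR = (1/n) * sum(1 / rank)` of each positive edge's score rank among
#' its negative competitors (rank 1 = highest score).
#'
#' @param rank_list integer ranks, all >= 1.
#' @return MRR in (0, 1].
#' @export
mean_reciprocal_rank <- function(rank_list) {
  if (!length(rank_list)) stop("value error: empty rank list")
  if (any(rank_list < 1)) stop("value error: ranks must be >= 1")
  mean(1 / rank_list)
}

# Ranks of eval positives among their negatives under embedding H:
# competition ranking, the positive wins ties.
eval_ranks <- function(H, eval_pos, eval_neg) {
  s_pos <- pair_similarities(H, eval_pos)
  sizes <- vapply(eval_neg, nrow, 0L)
  neg_all <- do.call(rbind, eval_neg)
  if (is.null(neg_all) || !nrow(neg_all)) return(rep(1L, nrow(eval_pos)))
  s_neg <- pair_similarities(H, neg_all)
  grp <- rep(seq_along(eval_neg), sizes)
  beaten <- s_neg > s_pos[grp]
  counts <- rep(0L, nrow(eval_pos))
  tab <- tapply(beaten, grp, sum)
  counts[as.integer(names(tab))] <- as.integer(tab)
  1L + counts
}

# Sample negatives for evaluation positives (e.g. held-out edges): per
# endpoint, gamma non-neighbors of the training graph, additionally
# excluding the eval partner and any other eval edge at that endpoint.
sample_eval_negatives <- function(g, eval_pos, gamma, seed) {
  m <- length(g$nodes)
  nbr <- graph_neighbors(g)
  forbidden <- split(c(eval_pos[, 2L], eval_pos[, 1L]),
                     factor(c(eval_pos[, 1L], eval_pos[, 2L]), levels = seq_len(m)))
  with_seed(seed, lapply(seq_len(nrow(eval_pos)), function(k) {
    out <- lapply(eval_pos[k, ], function(v) {
      cand <- setdiff(seq_len(m), c(v, nbr[[v]], forbidden[[v]]))
      take <- min(gamma, length(cand))
      if (take < 1L) return(matrix(integer(), 0L, 2L))
      partners <- if (length(cand) == 1L) cand else sample(cand, take)
      cbind(rep.int(v, take), partners)
    })
    do.call(rbind, out)
  }))
}

#' Train the link-prediction model
#'
#' Full-batch gradient descent on the negative-sampling loss through the
#' propagation layers. Each epoch: propagate, compute loss and its gradient
#' with respect to every layer's weight matrix, take a step of size `lr`,
#' and score the model by MRR — ranking each evaluation positive (held-out
#' edges when `eval_heldout` is given, otherwise a validation split of the
#' positives) against its negatives. Training stops when the absolute loss
#' change between adjacent epochs falls below `delta` or at `max_epochs`
#' (warned); the returned state carries the parameters of the best-MRR epoch.
#'
#' @param g training `gene_graph`.
#' @param params0 initial [gnn_params()].
#' @param samples a [build_link_samples()] result for `g`.
#' @param lr learning rate (> 0).
#' @param delta loss-change stopping tolerance (> 0).
#' @param max_epochs epoch cap (>= 1).
#' @param eval_heldout optional [weighted_edge_list()] of true edges absent
#'   from `g`, used for MRR model selection.
#' @param valid_fraction fraction of positives used for MRR when no held-out
#'   edges are supplied.
#' @return A `train_state`: list with `best_params`, `best_mrr`,
#'   `best_epoch`, `epoch`, `loss`, `delta`, `converged`, and `history`
#'   (data.frame epoch/loss/mrr).
#' @export
train_link_model <- function(g, params0, samples, lr = 0.01, delta = 1e-4,
                             max_epochs = 200, eval_heldout = NULL,
                             valid_fraction = 0.2) {
  stopifnot(lr > 0, delta > 0, max_epochs >= 1)
  if (!is.null(eval_heldout)) {
    keep <- eval_heldout$gene_a %in% g$nodes & eval_heldout$gene_b %in% g$nodes
    ep <- cbind(match(eval_heldout$gene_a[keep], g$nodes),
                match(eval_heldout$gene_b[keep], g$nodes))
    if (!nrow(ep)) stop("eval_heldout shares no gene pair with the graph")
    eval_pos <- ep
    eval_neg <- sample_eval_negatives(g, eval_pos, samples$gamma,
                                      seed = samples$seed + 1L)
  } else {
    n_val <- max(1L, round(valid_fraction * nrow(samples$pos)))
    val_idx <- with_seed(samples$seed + 2L,
                         sort(sample.int(nrow(samples$pos), n_val)))
    eval_pos <- samples$pos[val_idx, , drop = FALSE]
    eval_neg <- samples$neg[val_idx]
  }

  params <- params0
  history <- data.frame(epoch = integer(), loss = numeric(), mrr = numeric())
  best_mrr <- -Inf
  best_params <- params
  best_epoch <- 0L
  prev_loss <- NA_real_
  converged <- FALSE
  epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    fwd <- propagate(g, params, keep_cache = TRUE)
    H <- fwd$H
    loss <- link_loss(samples, H)
    if (!is.finite(loss)) stop("training error: non-finite loss at epoch ", epoch)
    mrr <- mean_reciprocal_rank(eval_ranks(H, eval_pos, eval_neg))
    history <- rbind(history, data.frame(epoch = epoch, loss = loss, mrr = mrr))
    if (mrr > best_mrr) {
      best_mrr <- mrr
      best_params <- params
      best_epoch <- epoch
    }
    if (!is.na(prev_loss) && abs(loss - prev_loss) < delta) {
      converged <- TRUE
      break
    }
    prev_loss <- loss
    dH <- link_loss_grad(samples, H)
    dW <- propagate_backward(params, fwd, dH)
    for (K in seq_along(params$weights))
      params$weights[[K]] <- params$weights[[K]] - lr * dW[[K]]
  }
  if (!converged)
    warning("train_link_model: max_epochs (", max_epochs,
            ") reached without loss-change < delta; best snapshot returned")
  structure(list(best_params = best_params, best_mrr = best_mrr,
                 best_epoch = best_epoch, epoch = epoch,
                 loss = history$loss[nrow(history)], delta = delta,
                 converged = converged, history = history),
            class = "train_state")
}

# Gradient of link_loss with respect to the embedding matrix H.
link_loss_grad <- function(samples, H) {
  n_pos <- nrow(samples$pos)
  neg_all <- do.call(rbind, samples$neg)
  pairs <- rbind(samples$pos, neg_all)
  s <- pair_similarities(H, pairs)
  sig <- logistic(s)
  # d/ds of -log sigma(s) is sigma(s) - 1; of -log sigma(-s) is sigma(s)
  coef <- c(sig[seq_len(n_pos)] - 1,
            if (nrow(pairs) > n_pos) sig[-seq_len(n_pos)]) / n_pos
  nrm <- row_norms(H)
  ia <- pairs[, 1L]; ib <- pairs[, 2L]
  ok <- nrm[ia] > 0 & nrm[ib] > 0
  safe_a <- pmax(nrm[ia], .Machine$double.eps)
  safe_b <- pmax(nrm[ib], .Machine$double.eps)
  Ha <- H[ia, , drop = FALSE] / safe_a
  Hb <- H[ib, , drop = FALSE] / safe_b
  # d sim / d h_a = (unit(h_b) - s unit(h_a)) / ||h_a||, and symmetrically
  ga <- coef * (Hb - s * Ha) / safe_a
  gb <- coef * (Ha - s * Hb) / safe_b
  ga[!ok, ] <- 0
  gb[!ok, ] <- 0
  acc <- rowsum(rbind(ga, gb), group = c(ia, ib))
  dH <- matrix(0, nrow(H), ncol(H))
  dH[as.integer(rownames(acc)), ] <- acc
  dH
}

#' Augment the graph with predicted links
#'
#' Scores candidate non-adjacent node pairs by the logistic-transformed
#' cosine similarity of their embeddings and adds every pair with confidence
#' `sigma(sim) >= theta` as a new edge weighted by that confidence. Original
#' edges and weights are untouched, so the result G* has at least as many
#' edges as G.
#'
#' @param g a `gene_graph`.
#' @param emb embedding matrix from the best trained parameters.
#' @param theta confidence threshold in (0, 1]; note `sigma(sim) <=
#'   sigma(1) ~ 0.731`, so thresholds above that disable augmentation
#'   (`theta = 1` is the no-augmentation ablation arm).
#' @param candidate_scope `"two_hop"` (default: only non-adjacent pairs
#'   sharing a neighbor are scored) or `"all_pairs"`.
#' @return a new `gene_graph` G*.
#' @export
augment_graph <- function(g, emb, theta = 0.7,
                          candidate_scope = c("two_hop", "all_pairs")) {
  candidate_scope <- match.arg(candidate_scope)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  m <- length(g$nodes)
  B <- g$A != 0
  if (candidate_scope == "two_hop") {
    reach2 <- Matrix::tcrossprod(B)  # shared-neighbor counts
    cand <- Matrix::which(Matrix::triu(reach2, k = 1) != 0, arr.ind = TRUE)
  } else {
    cand <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  }
  if (nrow(cand)) {
    adj <- as.logical(B[cand])
    cand <- cand[!adj, , drop = FALSE]
  }
  A_new <- g$A
  if (nrow(cand)) {
    conf <- logistic(pair_similarities(emb, cand))
    add <- conf >= theta
    if (any(add)) {
      ii <- cand[add, 1L]; jj <- cand[add, 2L]; ww <- conf[add]
      A_new <- A_new + Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                                            x = rep(ww, 2L), dims = c(m, m))
      gnnsc_log("augment_graph: added %d predicted edge(s)", sum(add))
    }
  }
  dimnames(A_new) <- list(g$nodes, g$nodes)
  structure(list(nodes = g$nodes, A = A_new, H0 = g$H0), class = "gene_graph")
}
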