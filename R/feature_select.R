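#' Specify a per-cluster gene scorer
#'
#' Registry of embedded scorers used to weight genes within a cluster:
#' \describe{
#'   \item{linear}{ordinary least squares of the labels on the cluster's
#'     standardized genes fitted jointly; score = |coefficient|. Singular
#'     fits (more genes than samples, collinearity) fall back to ridge
#'     (glmnet, alpha = 0) with a logged note.}
#'   \item{logistic}{ridge-regularized logistic regression (glmnet,
#'     alpha = 0); score = |coefficient|.}
#'   \item{corr}{absolute Pearson correlation of each gene with the labels;
#'     constant genes score 0.}
#'   \item{rf_importance}{random-forest mean decrease in node impurity.}
#'   \item{rfe_rank}{recursive feature elimination with a linear SVM:
#'     genes are eliminated one at a time by smallest |weight|; score =
#'     n_genes - elimination rank, so the survivor scores highest.}
#' }
#'
#' @param name scorer name.
#' @param params list of scorer settings; `joint = FALSE` switches linear /
#'   logistic to independent per-gene fits; `lambda` sets the ridge penalty
#'   (default 0.01); `ntree` the forest size (default 500).
#' @param seed integer seed for stochastic scorers.
#' @return A `scorer_spec`.
#' @export
scorer_spec <- function(name = c("linear", "logistic", "corr",
                                 "rf_importance", "rfe_rank"),
                        params = list(), seed = 1) {
  name <- match.arg(name)
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "scorer_spec")
}

#' Score the genes of one cluster
#'
#' Applies the scorer to the sub-dataset restricted to `genes` and returns
#' one non-negative score per gene. Linear/logistic/corr standardize genes
#' first, so scores are invariant to per-gene affine rescaling.
#'
#' @param ds an [expression_dataset()].
#' @param genes character vector of gene IDs (subset of the dataset's).
#' @param scorer a [scorer_spec()].
#' @return named numeric vector of scores, one per gene.
#' @export
score_subcluster <- function(ds, genes, scorer = scorer_spec("linear")) {
  genes <- as.character(genes)
  if (!length(genes)) stop("no genes to score")
  missing <- setdiff(genes, colnames(ds$X))
  if (length(missing))
    stop("genes absent from dataset: ", paste(utils::head(missing, 5), collapse = ", "))
  X <- ds$X[, genes, drop = FALSE]
  y <- ds$y
  scores <- switch(
    scorer$name,
    corr = score_corr(X, y),
    linear = score_linear(X, y, scorer),
    logistic = score_logistic(X, y, scorer),
    rf_importance = score_rf(X, y, scorer),
    rfe_rank = score_rfe(X, y, scorer)
  )
  pmax(stats::setNames(as.numeric(scores), genes), 0)
}

score_corr <- function(X, y) {
  apply(X, 2, function(col) {
    if (stats::sd(col) == 0) return(0)
    abs(stats::cor(col, y))
  })
}

score_linear <- function(X, y, scorer) {
  joint <- scorer$params$joint %||% TRUE
  Xs <- zscore_cols(X)
  if (!joint) {
    return(abs(apply(Xs, 2, function(col) {
      if (all(col == 0)) return(0)
      stats::coef(stats::lm.fit(cbind(1, col), y))[2L]
    })))
  }
  p <- ncol(Xs)
  Xd <- cbind(1, Xs)
  fit_ok <- nrow(Xs) > p && qr(Xd)$rank == p + 1L
  if (fit_ok) {
    abs(stats::coef(stats::lm.fit(Xd, y))[-1L])
  } else {
    gnnsc_log("score_subcluster: singular joint linear fit (%d genes, %d samples); ridge fallback",
              p, nrow(Xs))
    ridge_coefs(Xs, y, family = "gaussian", lambda = scorer$params$lambda %||% 0.01)
  }
}

score_logistic <- function(X, y, scorer) {
  joint <- scorer$params$joint %||% TRUE
  Xs <- zscore_cols(X)
  lambda <- scorer$params$lambda %||% 0.01
  if (!joint) {
    return(abs(apply(Xs, 2, function(col) {
      if (all(col == 0)) return(0)
      suppressWarnings(stats::coef(stats::glm.fit(cbind(1, col), y,
                                                  family = stats::binomial()))[2L])
    })))
  }
  ridge_coefs(Xs, y, family = "binomial", lambda = lambda)
}

ridge_coefs <- function(Xs, y, family, lambda) {
  # glmnet needs >= 2 columns; pad a constant (zero-variance) dummy if needed
  padded <- ncol(Xs) == 1L
  Xin <- if (padded) cbind(Xs, 0) else Xs
  fit <- glmnet::glmnet(Xin, y, family = family, alpha = 0, lambda = lambda,
                        standardize = FALSE)
  co <- abs(as.numeric(stats::coef(fit))[-1L])
  if (padded) co <- co[1L]
  co
}

score_rf <- function(X, y, scorer) {
  ntree <- scorer$params$ntree %||% 500
  if (ncol(X) == 1L) {
    # importance of a single predictor is degenerate; fall back to |corr|
    return(score_corr(X, y))
  }
  rf <- with_seed(scorer$seed,
                  randomForest::randomForest(X, factor(y), ntree = ntree,
                                             importance = FALSE))
  as.numeric(randomForest::importance(rf)[, 1L])
}

score_rfe <- function(X, y, scorer) {
  p <- ncol(X)
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  Xs <- zscore_cols(X)
  remaining <- seq_len(p)
  elim_rank <- integer(p)  # 1 = eliminated first
  step <- 0L
  while (length(remaining) > 1L) {
    w <- svm_weights(Xs[, remaining, drop = FALSE], y)
    drop_local <- which.min(abs(w))
    step <- step + 1L
    elim_rank[remaining[drop_local]] <- step
    remaining <- remaining[-drop_local]
  }
  elim_rank[remaining] <- p  # survivor eliminated "last"
  # final RFE rank: 1 = survivor, p = first eliminated; score = p - rank
  final_rank <- p - elim_rank + 1L
  p - final_rank
}

svm_weights <- function(Xs, y) {
  fit <- e1071::svm(Xs, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  w <- t(fit$coefs) %*% fit$SV
  as.numeric(w)
}

#' Select one biomarker per cluster
#'
#' Scores every cluster's genes with the scorer and takes the argmax-score
#' gene of each cluster as that cluster's biomarker. Ties are broken by
#' higher expression variance, then lexicographically smaller gene ID.
#' Clusters with no gene present in the dataset are skipped with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param ca a [partition_graph()] result (or any list with a `clusters`
#'   element of gene-ID vectors).
#' @param scorer a [scorer_spec()].
#' @return A `feature_ranking`: list with `entries` (data.frame gene_id /
#'   cluster_id / score, sorted by score descending) and `selected`
#'   (character vector, one top gene per cluster, ordered by score
#'   descending).
#' @export
select_biomarkers <- function(ds, ca, scorer = scorer_spec("linear")) {
  clusters <- ca$clusters
  entries <- list()
  selected <- character()
  sel_scores <- numeric()
  for (v in seq_along(clusters)) {
    genes <- intersect(clusters[[v]], colnames(ds$X))
    if (!length(genes)) {
      warning("cluster ", v - 1L, " has no gene present in the dataset; skipped")
      next
    }
    sc <- score_subcluster(ds, genes, scorer)
    vars <- apply(ds$X[, genes, drop = FALSE], 2, stats::var)
    ord <- order(-sc, -vars, genes)
    entries[[length(entries) + 1L]] <-
      data.frame(gene_id = genes[ord], cluster_id = v - 1L,
                 score = as.numeric(sc[ord]), stringsAsFactors = FALSE)
    selected <- c(selected, genes[ord][1L])
    sel_scores <- c(sel_scores, sc[ord][1L])
  }
  if (!length(entries)) stop("no cluster contained dataset genes")
  ent <- do.call(rbind, entries)
  vars_all <- apply(ds$X[, ent$gene_id, drop = FALSE], 2, stats::var)
  ord <- order(-ent$score, -vars_all, ent$gene_id)
  ent <- ent[ord, , drop = FALSE]
  rownames(ent) <- NULL
  sel_ord <- order(-sel_scores, selected)
  structure(list(entries = ent, selected = selected[sel_ord]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking: %d genes ranked, %d selected biomarkers\n",
              nrow(x$entries), length(x$selected)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
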