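#' Assemble a pipeline configuration
#'
#' Collects every stage's tunable settings with their defaults. The
#' configuration plus the seed fully determines a run.
#'
#' @param seed global integer seed; stage seeds are derived from it.
#' @param gnn list: `layers` (default 10), `hidden_dim` (32), `activation`
#'   ("relu").
#' @param link list: `gamma` (5), `lr` (0.01), `delta` (1e-4), `max_epochs`
#'   (200), `theta` (0.7), `scope` ("two_hop").
#' @param spectral list: `mu` (5), `omega` ("auto"), `row_normalize` (TRUE),
#'   `restarts` (10).
#' @param select list: `scorer` ("linear"), `scorer_params` (list()).
#' @param eval list: `k` (5 folds), `classifier` ("svm_linear").
#' @param keep_isolated,scale_states graph-construction flags (see
#'   [build_gene_graph()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, gnn = list(), link = list(),
                            spectral = list(), select = list(), eval = list(),
                            keep_isolated = TRUE, scale_states = TRUE) {
  cfg <- list(
    seed = as.integer(seed),
    keep_isolated = keep_isolated,
    scale_states = scale_states,
    gnn = utils::modifyList(list(layers = 10, hidden_dim = 32,
                                 activation = "relu"), gnn),
    link = utils::modifyList(list(gamma = 5, lr = 0.01, delta = 1e-4,
                                  max_epochs = 200, theta = 0.7,
                                  scope = "two_hop"), link),
    spectral = utils::modifyList(list(mu = 5, omega = "auto",
                                      row_normalize = TRUE, restarts = 10),
                                 spectral),
    select = utils::modifyList(list(scorer = "linear", scorer_params = list()),
                               select),
    eval = utils::modifyList(list(k = 5, classifier = "svm_linear"), eval)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# Deterministic stage seeds derived from the global seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(gnn = 101L, link = 211L, spectral = 307L, select = 401L,
               eval = 503L, folds = 601L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483629L
}

# Stratified k-fold assignment: within each class, a seeded shuffle is dealt
# round-robin to folds, so every fold contains both classes.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# AUC of scores for labels y (1 = positive), Mann-Whitney convention:
# tied scores contribute 1/2.
auc_scores <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated classification of a gene panel
#'
#' Stratified k-fold CV of an SVM trained on the selected genes only. Each
#' fold standardizes genes on its training split, fits the SVM (linear
#' kernel, cost 1, by default), and scores accuracy, sensitivity (recall of
#' class 1), specificity (recall of class 0), and AUC of the decision
#' values.
#'
#' @param ds an [expression_dataset()].
#' @param features character vector of gene IDs to classify with.
#' @param k number of folds (each class must have >= k samples).
#' @param classifier `"svm_linear"` or `"svm_rbf"`.
#' @param seed integer seed for the fold assignment.
#' @return A `cv_result`: list with `per_fold` (data.frame accuracy /
#'   sensitivity / specificity / auc), `means` (named vector of the four
#'   averages), `k`, `seed`.
#' @export
cross_validate <- function(ds, features, k = 5,
                           classifier = c("svm_linear", "svm_rbf"), seed = 1) {
  classifier <- match.arg(classifier)
  features <- as.character(features)
  if (!length(features)) stop("features must be non-empty")
  missing <- setdiff(features, colnames(ds$X))
  if (length(missing)) stop("features absent from dataset: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (k < 2) stop("k must be >= 2")
  if (min(table(ds$y)) < k) stop("each class needs at least k samples")
  folds <- stratified_folds(ds$y, k, seed)
  X <- ds$X[, features, drop = FALSE]
  y <- ds$y
  kern <- if (classifier == "svm_linear") "linear" else "radial"
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)), kernel = kern,
                      cost = 1, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    pred <- as.integer(as.character(pr))
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient decision values so that higher favors class 1
    if (startsWith(colnames(attr(pr, "decision.values"))[1L], "0")) dv <- -dv
    yt <- y[te]
    data.frame(
      accuracy = mean(pred == yt),
      sensitivity = if (any(yt == 1L)) mean(pred[yt == 1L] == 1L) else NA_real_,
      specificity = if (any(yt == 0L)) mean(pred[yt == 0L] == 0L) else NA_real_,
      auc = if (length(unique(yt)) == 2L) auc_scores(dv, yt) else NA_real_
    )
  }))
  means <- colMeans(per_fold, na.rm = TRUE)
  structure(list(per_fold = per_fold, means = means, k = k,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%d-fold): acc %.4f sens %.4f spec %.4f auc %.4f\n",
              x$k, x$means["accuracy"], x$means["sensitivity"],
              x$means["specificity"], x$means["auc"]))
  invisible(x)
}

#' Run the full biomarker-selection pipeline
#'
#' Executes, in order: graph construction, layered propagation, link-sample
#' construction, link-model training with MRR model selection, graph
#' augmentation with predicted edges (G*), re-propagation on G* with the
#' best parameters, Gaussian similarity of the embeddings, normalized
#' spectral clustering into `mu` groups, per-cluster biomarker selection,
#' and cross-validated SVM evaluation of the selected panel. Fully
#' reproducible from (config, seed).
#'
#' @param ds an [expression_dataset()].
#' @param edges a [weighted_edge_list()].
#' @param cfg a [pipeline_config()].
#' @param heldout_edges optional [weighted_edge_list()] of true edges absent
#'   from `edges`, used for MRR model selection instead of a validation
#'   split.
#' @param out_dir optional run directory; when given, writes
#'   `config.resolved.json`, `ranking.tsv`, `metrics.tsv`,
#'   `train_history.tsv`, and `log.txt`.
#' @return list with `ranking` (a `feature_ranking`), `cv` (a `cv_result`),
#'   `train` (the `train_state`), `graph`, `gstar`, `assignment`,
#'   `embeddings`, `config`.
#' @export
run_pipeline <- function(ds, edges, cfg = pipeline_config(),
                         heldout_edges = NULL, out_dir = NULL) {
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    gnnsc_log("%s", line)
  }
  stage <- "build_gene_graph"
  res <- tryCatch({
    g <- build_gene_graph(ds, edges, keep_isolated = cfg$keep_isolated,
                          scale_states = cfg$scale_states)
    note("graph: %d nodes, %d edges", length(g$nodes), graph_edge_count(g))

    stage <- "train_link_model"
    params0 <- gnn_params(input_dim = ncol(g$H0), n_layers = cfg$gnn$layers,
                          hidden_dim = cfg$gnn$hidden_dim,
                          activation = cfg$gnn$activation,
                          seed = stage_seed(cfg$seed, "gnn"))
    samples <- build_link_samples(g, gamma = cfg$link$gamma,
                                  seed = stage_seed(cfg$seed, "link"))
    train <- train_link_model(g, params0, samples, lr = cfg$link$lr,
                              delta = cfg$link$delta,
                              max_epochs = cfg$link$max_epochs,
                              eval_heldout = heldout_edges)
    note("link model: best MRR %.4f at epoch %d (%d epochs run)",
         train$best_mrr, train$best_epoch, train$epoch)

    stage <- "augment_graph"
    emb_g <- propagate(g, train$best_params)
    gstar <- augment_graph(g, emb_g, theta = cfg$link$theta,
                           candidate_scope = cfg$link$scope)
    note("G*: %d edges (was %d)", graph_edge_count(gstar), graph_edge_count(g))

    stage <- "spectral_cluster"
    emb <- propagate(gstar, train$best_params)
    sim <- gaussian_similarity(emb, omega = cfg$spectral$omega)
    se <- spectral_embed(sim, mu = cfg$spectral$mu,
                         row_normalize = cfg$spectral$row_normalize)
    labels <- cluster_rows(se, mu = cfg$spectral$mu,
                           seed = stage_seed(cfg$seed, "spectral"),
                           restarts = cfg$spectral$restarts)
    ca <- partition_graph(gstar, labels)

    stage <- "select_biomarkers"
    scorer <- scorer_spec(cfg$select$scorer, params = cfg$select$scorer_params,
                          seed = stage_seed(cfg$seed, "select"))
    ranking <- select_biomarkers(ds, ca, scorer)
    note("selected biomarkers: %s", paste(ranking$selected, collapse = ", "))

    stage <- "cross_validate"
    cv <- cross_validate(ds, ranking$selected, k = cfg$eval$k,
                         classifier = cfg$eval$classifier,
                         seed = stage_seed(cfg$seed, "folds"))
    note("CV means: acc %.4f sens %.4f spec %.4f auc %.4f",
         cv$means["accuracy"], cv$means["sensitivity"],
         cv$means["specificity"], cv$means["auc"])

    list(ranking = ranking, cv = cv, train = train, graph = g, gstar = gstar,
         assignment = ca, embeddings = emb, config = cfg)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir, log_lines)
  res
}

write_run_artifacts <- function(res, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(res$config), file.path(out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_ranking(res$ranking, file.path(out_dir, "ranking.tsv"))
  met <- res$cv$per_fold
  met$fold <- seq_len(nrow(met))
  met <- rbind(met, data.frame(t(c(colMeans(met[, 1:4], na.rm = TRUE))),
                               fold = NA))
  met_out <- data.frame(fold = ifelse(is.na(met$fold), "mean", met$fold),
                        lapply(met[, c("accuracy", "sensitivity",
                                       "specificity", "auc")],
                               function(v) sprintf("%.10g", v)))
  utils::write.table(met_out, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hist_out <- res$train$history
  hist_out$loss <- sprintf("%.10g", hist_out$loss)
  hist_out$mrr <- sprintf("%.10g", hist_out$mrr)
  utils::write.table(hist_out, file.path(out_dir, "train_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed: %d", res$config$seed), log_lines),
             file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Compare the pipeline against baseline feature selectors
#'
#' For each panel size m: (a) the full pipeline with `mu = m`; (b) the
#' pipeline with augmentation disabled (theta forced to its upper bound so
#' G* = G); (c) each baseline scorer applied to all genes with the top-m
#' taken. All arms share one trained link model per variant and one fold
#' assignment, so comparisons are paired.
#'
#' @param ds,edges,cfg as in [run_pipeline()].
#' @param feature_counts integer vector of panel sizes m.
#' @param baselines list of [scorer_spec()]s applied to all genes.
#' @return long-format data.frame with columns `method`, `m`, `metric`,
#'   `value` (methods: `pipeline`, `pipeline_no_augment`, baseline scorer
#'   names).
#' @export
compare_with_baselines <- function(ds, edges, cfg = pipeline_config(),
                                   feature_counts = 1:15,
                                   baselines = list(scorer_spec("corr"))) {
  feature_counts <- feature_counts[feature_counts >= 1]
  skip <- feature_counts > n_genes(ds)
  if (any(skip)) {
    warning("skipping m > number of genes: ", paste(feature_counts[skip], collapse = ", "))
    feature_counts <- feature_counts[!skip]
  }
  g <- build_gene_graph(ds, edges, keep_isolated = cfg$keep_isolated,
                        scale_states = cfg$scale_states)
  params0 <- gnn_params(input_dim = ncol(g$H0), n_layers = cfg$gnn$layers,
                        hidden_dim = cfg$gnn$hidden_dim,
                        activation = cfg$gnn$activation,
                        seed = stage_seed(cfg$seed, "gnn"))
  samples <- build_link_samples(g, gamma = cfg$link$gamma,
                                seed = stage_seed(cfg$seed, "link"))
  train <- train_link_model(g, params0, samples, lr = cfg$link$lr,
                            delta = cfg$link$delta,
                            max_epochs = cfg$link$max_epochs)
  emb_g <- propagate(g, train$best_params)
  gstar <- augment_graph(g, emb_g, theta = cfg$link$theta,
                         candidate_scope = cfg$link$scope)
  emb_star <- propagate(gstar, train$best_params)
  sim_star <- gaussian_similarity(emb_star, omega = cfg$spectral$omega)
  sim_g <- gaussian_similarity(emb_g, omega = cfg$spectral$omega)
  fold_seed <- stage_seed(cfg$seed, "folds")
  scorer <- scorer_spec(cfg$select$scorer, params = cfg$select$scorer_params,
                        seed = stage_seed(cfg$seed, "select"))

  arm_panel <- function(gr, simmat, m) {
    se <- spectral_embed(simmat, mu = m, row_normalize = cfg$spectral$row_normalize)
    labels <- cluster_rows(se, mu = m, seed = stage_seed(cfg$seed, "spectral"),
                           restarts = cfg$spectral$restarts)
    ca <- partition_graph(gr, labels)
    select_biomarkers(ds, ca, scorer)$selected
  }
  baseline_scores <- lapply(baselines, function(b)
    score_subcluster(ds, colnames(ds$X), b))
  names(baseline_scores) <- vapply(baselines, `[[`, "", "name")

  rows <- list()
  add_rows <- function(method, m, panel) {
    cv <- cross_validate(ds, panel, k = cfg$eval$k,
                         classifier = cfg$eval$classifier, seed = fold_seed)
    for (metric in names(cv$means))
      rows[[length(rows) + 1L]] <<- data.frame(method = method, m = m,
                                               metric = metric,
                                               value = unname(cv$means[metric]))
    panel
  }
  panels <- list()
  for (m in feature_counts) {
    panels[[paste0("pipeline_", m)]] <-
      add_rows("pipeline", m, arm_panel(gstar, sim_star, m))
    panels[[paste0("noaug_", m)]] <-
      add_rows("pipeline_no_augment", m, arm_panel(g, sim_g, m))
    for (b in names(baseline_scores)) {
      sc <- baseline_scores[[b]]
      vars <- apply(ds$X, 2, stats::var)
      top <- colnames(ds$X)[order(-sc, -vars, colnames(ds$X))][seq_len(m)]
      panels[[paste0(b, "_", m)]] <- add_rows(b, m, top)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "panels") <- panels
  out
}

#' Per-biomarker group-difference report
#'
#' For each selected gene: group means and SDs, Wilcoxon rank-sum statistic
#' (sum of group-1 ranks), two-sided p-value (exact when both groups have
#' <= 12 samples and no ties, else normal approximation with tie
#' correction), and a significance star code: `*` p < 0.05, `**` p < 0.01,
#' `****` p < 0.0001.
#'
#' @param ds an [expression_dataset()].
#' @param selected character vector of gene IDs.
#' @return data.frame, one row per gene.
#' @export
biomarker_report <- function(ds, selected) {
  selected <- as.character(selected)
  missing <- setdiff(selected, colnames(ds$X))
  if (length(missing)) stop("genes absent from dataset: ",
                            paste(missing, collapse = ", "))
  g1 <- ds$y == 1L
  do.call(rbind, lapply(selected, function(gene) {
    x1 <- ds$X[g1, gene]
    x0 <- ds$X[!g1, gene]
    wt <- rank_sum_test(x1, x0)
    data.frame(gene_id = gene,
               mean_g1 = mean(x1), sd_g1 = stats::sd(x1),
               mean_g0 = mean(x0), sd_g0 = stats::sd(x0),
               rank_sum = wt$rank_sum, p_value = wt$p,
               stars = star_code(wt$p),
               stringsAsFactors = FALSE)
  }))
}

rank_sum_test <- function(x1, x0) {
  n1 <- length(x1)
  ties <- anyDuplicated(c(x1, x0)) > 0
  exact <- n1 <= 12 && length(x0) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x1, x0, exact = exact,
                                            correct = FALSE))
  # wilcox.test statistic is Mann-Whitney U; convert to the rank sum of x1
  rank_sum <- unname(wt$statistic) + n1 * (n1 + 1) / 2
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # identical groups: zero-variance normal approx
  list(rank_sum = rank_sum, p = min(p, 1))
}

star_code <- function(p) {
  if (p < 1e-4) "****" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
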