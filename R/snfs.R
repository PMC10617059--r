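#' Fit the social network feature selection pipeline
#'
#' Runs the three SNFS stages on a training dataset and fits the final
#' tuned RBF-SVM on the selected biomarkers:
#'
#' 1. score genes with each method in `fs_methods`, merge the rankings by
#'    mean rank, keep the top `candidate_percent` as candidates;
#' 2. reduce candidates to class-mean profiles, run k-means once per entry
#'    of `k_values`, and count co-occurrences into a weighted adjacency;
#' 3. detect communities (`cd_method`) in the co-occurrence graph, compute
#'    the corrected degree of domesticity with the `epsilon` correction, and
#'    keep the top `biomarker_percent` of every community.
#'
#' Every stochastic stage draws its seed deterministically from the master
#' `seed` and a stage tag, so the same call always reproduces the same fit
#' and stages shared between different method combinations (e.g. the same
#' feature-selection pair under different community detectors) see identical
#' random streams.
#'
#' @param x an [expression_dataset()], or a genes-by-samples matrix with
#'   `labels`.
#' @param labels class labels (two classes) when `x` is a plain matrix.
#' @param fs_methods feature-selection methods to rank with and merge; two
#'   or more of `"cs"`, `"ig"`, `"rf"`, `"svm_sqrt_rfe"`.
#' @param candidate_percent fraction of genes kept after rank merging.
#' @param n_bins discretization bins for the chi-square and information-gain
#'   filters.
#' @param rf_trees random-forest size for `"rf"` scoring.
#' @param svm_cost linear-SVM cost used during recursive elimination.
#' @param k_values k-means cluster counts; one clustering run per entry.
#' @param kmeans_restarts k-means++ restarts per clustering run.
#' @param edge_threshold minimum co-occurrence count for a network edge.
#' @param cd_method community detection method: `"louvain"`, `"walktrap"`
#'   or `"infomap"`.
#' @param biomarker_percent per-community selection fraction.
#' @param epsilon corrected-degree-of-domesticity correction constant.
#' @param seed master RNG seed.
#' @param rankings optional precomputed list of `ranked_genes` objects named
#'   by method (as produced by the same seed), reused instead of recomputing
#'   — the sweep front end uses this to share rankings across combinations.
#' @param svm_controls optional list overriding the final SVM tuning:
#'   elements `cost_grid`, `gamma_grid`, `n_folds`.
#' @return an object of class `snfs` with components `rankings`, `combined`,
#'   `candidates`, `profile`, `adjacency`, `graph`, `partition`, `metrics`,
#'   `biomarkers`, `svm` (the fitted classifier), `config` and `call`.
#'   Methods: [print.snfs()], [summary.snfs()], [coef.snfs()],
#'   [predict.snfs()], [plot.snfs()]; evaluate on held-out data with
#'   [snfs_evaluate()].
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, n_blocks = 6,
#'   block_size = 50, n_shifted_genes = 50, n_positive_blocks = 3,
#'   n_train = 60, n_test = 60, seed = 3))
#' fit <- snfs(sim$train, fs_methods = c("cs", "ig"),
#'   candidate_percent = 0.2, seed = 3)
#' fit
#' snfs_evaluate(fit, sim$test)
#' @export
snfs <- function(x, labels = NULL,
                 fs_methods = c("svm_sqrt_rfe", "rf"),
                 candidate_percent = 0.05, n_bins = 10L, rf_trees = 500L,
                 svm_cost = 1, k_values = c(3L, 4L, 5L),
                 kmeans_restarts = 10L, edge_threshold = 1L,
                 cd_method = "louvain", biomarker_percent = 0.10,
                 epsilon = 1e-6, seed = 1L, rankings = NULL,
                 svm_controls = list()) {
  data <- assert_two_classes(as_expr_dataset(x, labels))
  fs_methods <- match.arg(fs_methods, c("cs", "ig", "rf", "svm_sqrt_rfe"),
                          several.ok = TRUE)
  if (length(fs_methods) < 2L)
    stop("SNFS merges rankings: give at least two feature-selection methods")

  ## stage 1: rank and merge
  rankings <- rankings %||% list()
  for (m in fs_methods) {
    if (is.null(rankings[[m]]))
      rankings[[m]] <- score_method(m, data, n_bins = n_bins,
                                    rf_trees = rf_trees, svm_cost = svm_cost,
                                    seed = derive_seed(seed, "rank", m))
  }
  combined <- merge_ranks(rankings[fs_methods])
  candidates <- select_candidates(combined, candidate_percent)

  ## stage 2: class-mean profile and co-occurrence network
  profile <- class_mean_profile(data, candidates)
  adjacency <- cooccurrence_adjacency(
    profile, k_values = k_values, restarts = kmeans_restarts,
    seed = derive_seed(seed, "network", paste(fs_methods, collapse = "+")))

  ## stage 3: communities, corrected degree of domesticity, selection
  graph <- build_gene_graph(adjacency, edge_threshold)
  partition <- detect_communities(graph, cd_method,
                                  seed = derive_seed(seed, "cd", cd_method))
  metrics <- domesticity_metrics(graph, partition, epsilon)
  biomarkers <- select_biomarkers(metrics, biomarker_percent)

  ## final classifier on the selected genes
  xtr <- t(data$values[biomarkers$gene_ids, , drop = FALSE])
  svm <- rbf_tune_fit(xtr, data$labels,
                      cost_grid = svm_controls$cost_grid,
                      gamma_grid = svm_controls$gamma_grid,
                      n_folds = svm_controls$n_folds %||% 5L,
                      seed = derive_seed(seed, "svm"))

  structure(list(
    rankings = rankings, combined = combined, candidates = candidates,
    profile = profile, adjacency = adjacency, graph = graph,
    partition = partition, metrics = metrics, biomarkers = biomarkers,
    svm = svm, labels = data$labels,
    config = list(fs_methods = fs_methods,
                  candidate_percent = candidate_percent, n_bins = n_bins,
                  rf_trees = rf_trees, svm_cost = svm_cost,
                  k_values = k_values, kmeans_restarts = kmeans_restarts,
                  edge_threshold = edge_threshold, cd_method = cd_method,
                  biomarker_percent = biomarker_percent, epsilon = epsilon,
                  seed = seed),
    call = match.call()), class = "snfs")
}

#' @export
print.snfs <- function(x, ...) {
  cat("SNFS fit:", paste(x$config$fs_methods, collapse = "+"), "ranking,",
      x$config$cd_method, "communities\n")
  cat(sprintf("  %d genes -> %d candidates -> %d communities -> %d biomarkers\n",
              nrow(x$combined), length(x$candidates$gene_ids),
              x$partition$n_communities, length(x$biomarkers$gene_ids)))
  cat(sprintf("  final SVM: cost %g, gamma %g, CV accuracy %.4f, training accuracy %.4f\n",
              x$svm$cost, x$svm$gamma, x$svm$cv_accuracy,
              x$svm$train_accuracy))
  invisible(x)
}

#' Summary of a fitted SNFS pipeline
#'
#' @param object an `snfs` fit.
#' @param n_top how many top biomarkers to show.
#' @param ... unused.
#' @export
summary.snfs <- function(object, n_top = 10L, ...) {
  print(object)
  sizes <- table(object$metrics$community)
  cat("community sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  sel <- object$metrics[object$metrics$gene %in% object$biomarkers$gene_ids, ]
  sel <- sel[order(-sel$z_d, -sel$z_in, sel$gene), ]
  cat("top biomarkers by corrected degree of domesticity:\n")
  print(head(sel[, c("gene", "community", "z_in", "z_out", "z_d")], n_top),
        row.names = FALSE)
  invisible(list(communities = sizes, biomarkers = sel))
}

#' Selected-gene metrics of an SNFS fit
#'
#' Returns the corrected degree of domesticity of the selected biomarkers,
#' named by gene, ordered as selected.
#'
#' @param object an `snfs` fit.
#' @param ... unused.
#' @export
coef.snfs <- function(object, ...) {
  idx <- match(object$biomarkers$gene_ids, object$metrics$gene)
  stats::setNames(object$metrics$z_d[idx], object$metrics$gene[idx])
}

#' Predict classes or decision values for new samples
#'
#' @param object an `snfs` fit.
#' @param newdata an [expression_dataset()] or genes-by-samples matrix
#'   containing at least the selected biomarker genes.
#' @param type `"class"` for predicted labels, `"decision"` for continuous
#'   decision values oriented so that larger means the second class level.
#' @param ... unused.
#' @export
predict.snfs <- function(object, newdata, type = c("class", "decision"),
                         ...) {
  type <- match.arg(type)
  values <- if (inherits(newdata, "expr_dataset")) newdata$values
            else as.matrix(newdata)
  missing <- setdiff(object$biomarkers$gene_ids, rownames(values))
  if (length(missing))
    stop("new data is missing selected genes: ",
         paste(head(missing, 5), collapse = ", "))
  pred <- predict_snfs_svm(object$svm,
                           t(values[object$biomarkers$gene_ids, ,
                                    drop = FALSE]))
  if (type == "class") pred$class else pred$decision
}

#' Evaluate a fitted SNFS pipeline on held-out data
#'
#' Predicts the test samples with the classifier fitted by [snfs()] and
#' reports accuracy, sensitivity, specificity and AUC.
#'
#' @param object an `snfs` fit.
#' @param test an [expression_dataset()] with the same genes.
#' @param positive_label class treated as positive; defaults to the minority
#'   training class (second level on ties).
#' @return an `evaluation_report` (see [evaluate_classifier()]).
#' @export
snfs_evaluate <- function(object, test, positive_label = NULL) {
  stopifnot(inherits(object, "snfs"), inherits(test, "expr_dataset"))
  pred <- predict_snfs_svm(object$svm,
                           t(subset_features(test,
                                             object$biomarkers$gene_ids)))
  positive_label <- positive_label %||% default_positive(object$labels)
  report_metrics(truth = factor(test$labels, levels = object$svm$levels),
                 predicted = pred$class, decision = pred$decision,
                 positive = positive_label, fit = object$svm,
                 n_features = length(object$biomarkers$gene_ids))
}

#' Plot the co-occurrence network of an SNFS fit
#'
#' Vertices are candidate genes colored by community; selected biomarkers
#' are drawn larger with a black border.
#'
#' @param x an `snfs` fit.
#' @param ... forwarded to [igraph::plot.igraph()].
#' @export
plot.snfs <- function(x, ...) {
  g <- x$graph
  memb <- x$partition$membership[igraph::V(g)$name]
  sel <- igraph::V(g)$name %in% x$biomarkers$gene_ids
  pal <- grDevices::hcl.colors(max(memb), "Dark 3")
  igraph::plot.igraph(
    g, vertex.color = pal[memb], vertex.size = ifelse(sel, 6, 3),
    vertex.frame.color = ifelse(sel, "black", NA), vertex.label = NA,
    edge.width = igraph::E(g)$weight, ...)
  invisible(x)
}
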