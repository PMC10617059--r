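## Stage 1: per-method gene ranking, rank merging, candidate selection.

#' Ranked gene list
#'
#' Internal constructor shared by all scoring methods: orders genes by
#' decreasing score with ties broken lexicographically by gene identifier,
#' so every ranking is bit-reproducible.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param scores numeric scores, higher = more informative.
#' @param method method label.
#' @return a `ranked_genes` data.frame with columns `gene`, `score`, `rank`.
#' @keywords internal
ranked_list <- function(gene_ids, scores, method) {
  stopifnot(length(gene_ids) == length(scores))
  ord <- order(-scores, gene_ids)
  structure(data.frame(gene = gene_ids[ord], score = scores[ord],
                       rank = seq_along(ord), row.names = NULL),
            class = c("ranked_genes", "data.frame"), method = method)
}

#' @export
print.ranked_genes <- function(x, n = 6, ...) {
  cat("gene ranking (", attr(x, "method"), "), ", nrow(x), " genes; top:\n",
      sep = "")
  print.data.frame(head(x, n))
  invisible(x)
}

#' Equal-frequency discretization
#'
#' Assigns each value to one of `n_bins` equal-frequency bins. Ties are
#' resolved by position in the input (stable order), so the assignment is
#' deterministic; a constant vector maps to a single bin.
#'
#' @param x numeric vector.
#' @param n_bins number of bins, at least 2.
#' @return integer bin index per element, in `1:n_bins`.
#' @examples
#' discretize_ef(c(1, 2, 3, 4), 2)
#' @export
discretize_ef <- function(x, n_bins = 10L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n <- length(x)
  if (length(unique(x)) == 1L) return(rep(1L, n))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

# Bin all genes of a dataset at once: integer matrix, genes x samples.
discretize_matrix <- function(values, n_bins) {
  t(apply(values, 1L, discretize_ef, n_bins = n_bins))
}

# Per-gene (bin x class) counts: list of two genes x n_bins count matrices.
bin_class_counts <- function(bins, labels, n_bins) {
  lv <- levels(labels)
  lapply(lv, function(cl) {
    sub <- bins[, labels == cl, drop = FALSE]
    matrix(vapply(seq_len(n_bins), function(b) rowSums(sub == b),
                  numeric(nrow(bins))),
           nrow = nrow(bins), ncol = n_bins)
  })
}

#' Chi-square filter scores
#'
#' Pearson chi-square statistic of the (discretized gene) x (class)
#' contingency table, per gene. Genes with no variance fall into a single
#' bin and score 0. Higher scores mean stronger class association.
#'
#' @param data an [expression_dataset()] (or matrix plus `labels`).
#' @param labels class labels when `data` is a plain matrix.
#' @param n_bins equal-frequency bins used to discretize each gene.
#' @return a `ranked_genes` data.frame.
#' @export
chi_square_scores <- function(data, labels = NULL, n_bins = 10L) {
  data <- assert_two_classes(as_expr_dataset(data, labels))
  bins <- discretize_matrix(data$values, n_bins)
  cc <- bin_class_counts(bins, data$labels, n_bins)
  o1 <- cc[[1]]; o2 <- cc[[2]]
  m <- o1 + o2                       # bin margins per gene
  n1 <- sum(data$labels == levels(data$labels)[1])
  n <- ncol(data$values)
  e1 <- m * (n1 / n); e2 <- m * ((n - n1) / n)
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  stat <- rowSums(term(o1, e1) + term(o2, e2))
  ranked_list(rownames(data$values), stat, "cs")
}

#' Information-gain filter scores
#'
#' Mutual information between class and discretized gene expression, in
#' bits: `H(class) - H(class | bin)`. Zero-variance genes score 0.
#'
#' @inheritParams chi_square_scores
#' @return a `ranked_genes` data.frame.
#' @export
info_gain_scores <- function(data, labels = NULL, n_bins = 10L) {
  data <- assert_two_classes(as_expr_dataset(data, labels))
  bins <- discretize_matrix(data$values, n_bins)
  cc <- bin_class_counts(bins, data$labels, n_bins)
  o1 <- cc[[1]]; o2 <- cc[[2]]
  m <- o1 + o2
  n <- ncol(data$values)
  xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)
  n1 <- sum(data$labels == levels(data$labels)[1])
  h_class <- -xlog2x(n1 / n) - xlog2x(1 - n1 / n)
  # H(class | bin) = sum_b (m_b / n) * H(o1_b / m_b)
  p1 <- ifelse(m > 0, o1 / pmax(m, 1), 0)
  h_cond <- rowSums((m / n) * (-xlog2x(p1) - xlog2x(1 - p1)))
  ranked_list(rownames(data$values), h_class - h_cond, "ig")
}

#' Random-forest importance scores
#'
#' Mean-decrease-in-impurity (Gini) importance from a seeded random-forest
#' classifier over all genes.
#'
#' @inheritParams chi_square_scores
#' @param n_trees forest size.
#' @param seed RNG seed; the same seed always returns the same ranking.
#' @return a `ranked_genes` data.frame.
#' @export
rf_importance_scores <- function(data, labels = NULL, n_trees = 500L,
                                 seed = 1L) {
  data <- assert_two_classes(as_expr_dataset(data, labels))
  if (any(tabulate(data$labels) < 2L))
    stop("random-forest scoring needs at least 2 samples per class")
  rf <- with_seed(seed, randomForest::randomForest(
    x = t(data$values), y = data$labels, ntree = n_trees))
  imp <- rf$importance[, "MeanDecreaseGini"]
  ranked_list(rownames(data$values), as.numeric(imp), "rf")
}

#' SVM recursive feature elimination with square-root batches
#'
#' Repeatedly fits a linear support vector machine on the surviving genes,
#' scores each gene by its squared weight \eqn{w_j^2}, and eliminates the
#' `floor(sqrt(remaining))` worst-scoring genes (at least one) per
#' iteration. The final ranking is the reverse of the elimination order;
#' within an eliminated batch genes are ordered by weight. Internally the
#' linear Gram matrix over samples is computed once and downdated as genes
#' are removed, so the cost per iteration is one small SVM fit regardless
#' of gene count.
#'
#' @inheritParams chi_square_scores
#' @param svm_cost fixed soft-margin cost used for every elimination fit.
#' @return a `ranked_genes` data.frame (`score` is the reversed elimination
#'   position, higher = better).
#' @export
svm_sqrt_rfe_ranking <- function(data, labels = NULL, svm_cost = 1) {
  data <- assert_two_classes(as_expr_dataset(data, labels))
  x <- t(data$values)                       # samples x genes
  if (ncol(x) < 2L) stop("need at least 2 genes for recursive elimination")
  y <- droplevels(data$labels)
  genes <- colnames(x)
  surv <- seq_len(ncol(x))
  gram <- tcrossprod(x)
  eliminated <- integer(0)
  iter <- 0L
  while (length(surv) > 1L) {
    iter <- iter + 1L
    fit <- tryCatch({
      emb <- kernel_embedding(gram)
      e1071::svm(emb$features, y, kernel = "linear", cost = svm_cost,
                 scale = FALSE)
    }, error = function(e) stop("linear SVM failed at elimination iteration ",
                                iter, ": ", conditionMessage(e)))
    # w_j = sum_i (alpha_i y_i) x_ij over support vectors, in gene space
    w2 <- as.vector(crossprod(x[fit$index, surv, drop = FALSE],
                              fit$coefs))^2
    n_drop <- min(max(1L, floor(sqrt(length(surv)))), length(surv) - 1L)
    ord <- order(w2, genes[surv])           # worst first, ties by gene id
    drop_idx <- ord[seq_len(n_drop)]
    dropped <- surv[drop_idx]
    gram <- gram - tcrossprod(x[, dropped, drop = FALSE])
    eliminated <- c(eliminated, dropped)
    surv <- surv[-drop_idx]
  }
  ranking <- rev(c(eliminated, surv))       # best gene first
  ranked_list(genes[ranking], scores = rev(seq_along(ranking)),
              method = "svm_sqrt_rfe")
}

# Dispatcher used by the pipeline front ends.
score_method <- function(method, data, n_bins, rf_trees, svm_cost, seed) {
  switch(method,
         cs = chi_square_scores(data, n_bins = n_bins),
         ig = info_gain_scores(data, n_bins = n_bins),
         rf = rf_importance_scores(data, n_trees = rf_trees, seed = seed),
         svm_sqrt_rfe = svm_sqrt_rfe_ranking(data, svm_cost = svm_cost),
         stop("unknown feature-selection method: ", method))
}

#' Merge rankings by mean rank
#'
#' Borda-style combination: each gene's combined score is the arithmetic
#' mean of its rank positions (1 = best) across the input lists; genes are
#' then sorted by ascending mean rank, ties broken lexicographically by gene
#' identifier. All lists must cover the same gene set.
#'
#' @param ... two or more `ranked_genes` objects (or a single list of them).
#' @return a `ranked_genes` data.frame with an extra `mean_rank` column.
#' @export
merge_ranks <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1]], "ranked_genes"))
    lists <- lists[[1]]
  if (length(lists) < 2L) stop("need at least two rankings to merge")
  ref <- sort(lists[[1]]$gene)
  for (l in lists) {
    if (!identical(sort(l$gene), ref)) {
      diff <- union(setdiff(l$gene, ref), setdiff(ref, l$gene))
      stop("rankings cover different gene sets; symmetric difference: ",
           paste(sort(diff), collapse = ", "))
    }
  }
  ranks <- vapply(lists, function(l) l$rank[match(ref, l$gene)],
                  numeric(length(ref)))
  mean_rank <- rowMeans(ranks)
  methods <- vapply(lists, function(l) attr(l, "method") %||% "?", "")
  out <- ranked_list(ref, -mean_rank, paste(methods, collapse = "+"))
  out$mean_rank <- -out$score
  out
}

#' Select candidate genes from a combined ranking
#'
#' Keeps the top `ceiling(percent * p)` genes; a nonzero percentage never
#' selects zero genes.
#'
#' @param combined a `ranked_genes` object (typically from [merge_ranks()]).
#' @param percent fraction of genes to keep, in `(0, 1]`.
#' @return a `candidate_set`: list with `gene_ids`, `percent`,
#'   `source_methods`.
#' @export
select_candidates <- function(combined, percent) {
  stopifnot(inherits(combined, "ranked_genes"))
  if (percent <= 0 || percent > 1) stop("percent must lie in (0, 1]")
  k <- top_n_by_percent(nrow(combined), percent)
  structure(list(gene_ids = combined$gene[seq_len(k)], percent = percent,
                 source_methods = attr(combined, "method")),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate set:", length(x$gene_ids), "genes (",
      sprintf("%.1f%%", 100 * x$percent), "of the ranking, methods:",
      x$source_methods, ")\n")
  invisible(x)
}

#' Write a ranking to TSV
#'
#' Audit output: columns `gene`, `score`, `rank` (plus `mean_rank` for merged
#' lists).
#'
#' @param ranking a `ranked_genes` object.
#' @param path output file.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_genes"))
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
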