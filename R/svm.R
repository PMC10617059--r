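## Internal RBF-SVM engine.
##
## Every SVM in the package is solved by libsvm (via e1071) on a precomputed
## kernel. libsvm takes no kernel matrix directly, so the engine uses an
## exact reformulation: if K = R'R is the Cholesky factorization of the
## kernel matrix, a *linear* SVM on the rows of R' is the same optimization
## problem as the kernel SVM on K (row inner products reproduce K exactly),
## and kernel values of held-out or test samples are recovered by one
## triangular solve. The RBF squared-distance matrix between training
## samples is therefore computed once and every (cost, gamma) grid point
## reuses it, which makes cross-validated tuning on 10,000 genes as cheap
## as on ten.

# Squared Euclidean distances between rows of a and rows of b.
dist2_matrix <- function(a, b = NULL) {
  if (is.null(b)) b <- a
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Cholesky feature embedding of a PSD kernel matrix: rows of the returned
# `features` have pairwise inner products equal to k (up to the stabilizing
# ridge). `embed` maps a cross-kernel block (new x train) into the same
# feature space.
kernel_embedding <- function(k) {
  ridge <- 1e-8 * mean(diag(k))
  r <- chol(k + diag(ridge, nrow(k)))
  list(features = t(r),
       embed = function(k_new) t(backsolve(r, t(k_new), transpose = TRUE)))
}

# Stratified fold ids: within each class, samples are shuffled and dealt
# round-robin so every fold keeps the class proportions.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Decision values oriented so that larger means the second factor level.
# libsvm names the decision column "<pos>/<neg>" with positive values for
# <pos>; fall back to an empirical orientation if the labels make the name
# ambiguous.
oriented_decision <- function(pred, levels, truth = NULL) {
  dv <- attr(pred, "decision.values")
  pos <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  v <- as.vector(dv)
  if (pos %in% levels) return(if (pos == levels[2]) v else -v)
  if (!is.null(truth)) {
    s <- sign(mean(v[truth == levels[2]]) - mean(v[truth == levels[1]]))
    return(if (s >= 0) v else -v)
  }
  v
}

default_cost_grid <- function() 2^seq(-2, 8, by = 2)

# Median-heuristic gamma grid: centered on 1 / median squared distance so
# the kernel bandwidth tracks the feature count, spanning three octaves
# either side.
default_gamma_grid <- function(d2_train) {
  off <- d2_train[upper.tri(d2_train)]
  off <- off[off > 0]
  g0 <- if (length(off)) 1 / median(off) else 1
  g0 * 2^(-3:3)
}

# Grid-tune and fit an RBF SVM. x: samples x features. Returns an
# `snfs_svm` object carrying everything prediction needs.
rbf_tune_fit <- function(x, y, cost_grid = NULL, gamma_grid = NULL,
                         n_folds = 5L, seed = 1L) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("the SVM step needs exactly two classes")
  if (any(tabulate(y) < 2L)) stop("need at least 2 samples per class")
  d2 <- dist2_matrix(x)
  cost_grid <- sort(cost_grid %||% default_cost_grid())
  gamma_grid <- sort(gamma_grid %||% default_gamma_grid(d2))
  n_folds <- min(n_folds, min(tabulate(y)))
  folds <- with_seed(seed, stratified_folds(y, n_folds))
  cv <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                    KEEP.OUT.ATTRS = FALSE)
  cv$accuracy <- NA_real_
  if (nrow(cv) > 1L) {           # a single grid point needs no tuning
    for (g in gamma_grid) {
      emb <- kernel_embedding(exp(-g * d2))
      f <- emb$features
      for (cst in cost_grid) {
        correct <- 0L
        for (fd in seq_len(n_folds)) {
          tr <- folds != fd
          m <- tryCatch(
            e1071::svm(f[tr, , drop = FALSE], y[tr], kernel = "linear",
                       cost = cst, scale = FALSE),
            error = function(e) NULL)
          if (is.null(m)) next
          pr <- predict(m, f[!tr, , drop = FALSE])
          correct <- correct + sum(pr == y[!tr])
        }
        cv$accuracy[cv$cost == cst & cv$gamma == g] <- correct / length(y)
      }
    }
  }
  best <- cv[order(-cv$accuracy, cv$cost, cv$gamma), ][1L, ]
  emb <- kernel_embedding(exp(-best$gamma * d2))
  model <- e1071::svm(emb$features, y, kernel = "linear", cost = best$cost,
                      scale = FALSE)
  train_pred <- predict(model, emb$features)
  structure(list(model = model, x = x, embed = emb$embed,
                 levels = levels(y), cost = best$cost, gamma = best$gamma,
                 cv_accuracy = best$accuracy, cv_table = cv,
                 train_accuracy = mean(train_pred == y)),
            class = "snfs_svm")
}

# Predict on new samples (rows) with the same feature columns as training.
predict_snfs_svm <- function(fit, newx) {
  stopifnot(inherits(fit, "snfs_svm"))
  if (ncol(newx) != ncol(fit$x))
    stop("new data has ", ncol(newx), " features; the model was fitted on ",
         ncol(fit$x))
  k_new <- exp(-fit$gamma * dist2_matrix(newx, fit$x))
  f_new <- fit$embed(k_new)
  pr <- predict(fit$model, f_new, decision.values = TRUE)
  list(class = factor(as.character(pr), levels = fit$levels),
       decision = oriented_decision(pr, fit$levels))
}

#' Area under the ROC curve from continuous scores
#'
#' Pairwise (Mann-Whitney) AUC: the fraction of (positive, negative) sample
#' pairs in which the positive sample scores higher, with ties counting
#' one half. Computed via midranks, which is algebraically identical to the
#' pairwise sum.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels class labels.
#' @param positive the label treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels, positive) {
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC needs both positive and negative samples")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
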