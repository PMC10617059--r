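## Hold-out evaluation: stratified splitting, RBF-SVM tuning, and the
## accuracy / sensitivity / specificity / AUC report.

#' Stratified hold-out split
#'
#' Splits the samples into training and test partitions with per-class
#' proportional allocation: the training partition gets
#' `round(train_fraction * n)` samples, distributed across classes by
#' largest remainder so class prevalence is preserved as closely as integer
#' counts allow.
#'
#' @param data an [expression_dataset()].
#' @param train_fraction fraction of samples for training, in `(0, 1)`.
#' @param seed RNG seed; the same seed always yields the same split.
#' @return list with `train` and `test` expression datasets.
#' @export
stratified_holdout_split <- function(data, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(data, "expr_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  y <- data$labels
  n <- length(y)
  target <- round(train_fraction * n)
  counts <- table(y)
  raw <- train_fraction * as.numeric(counts)
  take <- floor(raw)
  short <- target - sum(take)
  if (short > 0) {
    extra <- order(-(raw - take))[seq_len(short)]
    take[extra] <- take[extra] + 1
  } else if (short < 0) {
    less <- order(raw - take)[seq_len(-short)]
    take[less] <- take[less] - 1
  }
  if (any(take < 1) || any(as.numeric(counts) - take < 1))
    stop("split would leave a class empty in one partition")
  train_idx <- with_seed(seed, unlist(lapply(seq_along(counts), function(i) {
    idx <- which(y == names(counts)[i])
    sample(idx, take[i])
  })))
  train_idx <- sort(train_idx)
  list(train = expression_dataset(data$values[, train_idx, drop = FALSE],
                                  y[train_idx]),
       test = expression_dataset(data$values[, -train_idx, drop = FALSE],
                                 y[-train_idx]))
}

#' Tune an RBF-kernel SVM by cross-validation
#'
#' Grid search over (cost, gamma) by stratified k-fold cross-validation on
#' the training data only, restricted to `feature_subset` when given. The
#' default grid is cost `2^{-2, 0, ..., 8}` crossed with a gamma grid
#' centered on the median-heuristic bandwidth `1 / median(squared sample
#' distance)` spanning `2^{-3}..2^{3}` around it; the heuristic keeps the
#' kernel sensible whether 10 or 10,000 genes are in play. Ties are broken
#' towards the smallest cost, then the smallest gamma.
#'
#' @param train an [expression_dataset()] (or matrix plus `labels`).
#' @param feature_subset optional character vector of gene ids.
#' @param labels class labels when `train` is a plain matrix.
#' @param cost_grid,gamma_grid optional explicit grids.
#' @param n_folds cross-validation folds (capped at the smaller class size).
#' @param seed RNG seed for fold assignment.
#' @return list with `cost`, `gamma`, `cv_accuracy` and the full `cv_table`.
#' @export
tune_rbf_svm <- function(train, feature_subset = NULL, labels = NULL,
                         cost_grid = NULL, gamma_grid = NULL, n_folds = 5L,
                         seed = 1L) {
  train <- assert_two_classes(as_expr_dataset(train, labels))
  x <- t(subset_features(train, feature_subset))
  fit <- rbf_tune_fit(x, train$labels, cost_grid, gamma_grid, n_folds, seed)
  list(cost = fit$cost, gamma = fit$gamma, cv_accuracy = fit$cv_accuracy,
       cv_table = fit$cv_table)
}

# Restrict a dataset to a feature subset (genes x samples matrix out).
subset_features <- function(data, feature_subset) {
  if (is.null(feature_subset)) return(data$values)
  feature_subset <- as.character(feature_subset)
  if (length(feature_subset) == 0L) stop("feature subset is empty")
  missing <- setdiff(feature_subset, rownames(data$values))
  if (length(missing))
    stop("features absent from the data: ",
         paste(head(missing, 5), collapse = ", "))
  data$values[feature_subset, , drop = FALSE]
}

# Default positive class: the minority class; ties go to the second level.
default_positive <- function(labels) {
  counts <- table(labels)
  lv <- levels(labels)
  if (counts[lv[1]] < counts[lv[2]]) lv[1] else lv[2]
}

#' Fit and evaluate an RBF SVM on a hold-out split
#'
#' Tunes (unless `params` is supplied), fits the RBF SVM on the training
#' samples restricted to `feature_subset`, predicts the test samples, and
#' reports confusion-based metrics for the declared positive class plus the
#' AUC computed from continuous decision values.
#'
#' @param train,test [expression_dataset()] objects over the same genes.
#' @param feature_subset character vector of gene ids (or a `biomarker_set`);
#'   `NULL` uses every gene (the whole-feature-set baseline).
#' @param params optional list with `cost` and `gamma` to skip tuning.
#' @param positive_label class treated as positive; defaults to the minority
#'   training class (second level on ties).
#' @param cost_grid,gamma_grid,n_folds,seed tuning controls, see
#'   [tune_rbf_svm()].
#' @return an `evaluation_report`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `confusion` (2x2 table), `n_features`,
#'   `train_accuracy`, `params`, `positive_label` and `decision_values`.
#' @export
evaluate_classifier <- function(train, test, feature_subset = NULL,
                                params = NULL, positive_label = NULL,
                                cost_grid = NULL, gamma_grid = NULL,
                                n_folds = 5L, seed = 1L) {
  stopifnot(inherits(train, "expr_dataset"), inherits(test, "expr_dataset"))
  assert_two_classes(train)
  if (inherits(feature_subset, "biomarker_set"))
    feature_subset <- feature_subset$gene_ids
  xtr <- t(subset_features(train, feature_subset))
  xte <- t(subset_features(test, feature_subset))
  positive_label <- positive_label %||% default_positive(train$labels)
  if (!positive_label %in% levels(train$labels))
    stop("positive_label is not one of the class labels")
  if (!is.null(params)) {
    cost_grid <- params$cost
    gamma_grid <- params$gamma
  }
  fit <- rbf_tune_fit(xtr, train$labels, cost_grid, gamma_grid, n_folds,
                      seed)
  pred <- predict_snfs_svm(fit, xte)
  report_metrics(truth = factor(test$labels, levels = fit$levels),
                 predicted = pred$class, decision = pred$decision,
                 positive = positive_label, fit = fit,
                 n_features = ncol(xtr))
}

# Assemble the evaluation report from predictions.
report_metrics <- function(truth, predicted, decision, positive, fit,
                           n_features) {
  lv <- levels(truth)
  negative <- setdiff(lv, positive)
  tp <- sum(predicted == positive & truth == positive)
  tn <- sum(predicted == negative & truth == negative)
  fp <- sum(predicted == positive & truth == negative)
  fn <- sum(predicted == negative & truth == positive)
  # decision values are oriented towards the second level; flip when the
  # declared positive class is the first
  dv <- if (positive == lv[2]) decision else -decision
  structure(list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc_from_scores(dv, truth, positive),
    confusion = table(predicted = predicted, truth = truth),
    n_features = n_features,
    train_accuracy = fit$train_accuracy,
    params = list(cost = fit$cost, gamma = fit$gamma,
                  cv_accuracy = fit$cv_accuracy),
    positive_label = positive,
    decision_values = dv), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "hold-out evaluation (%d features, positive = %s)\n", x$n_features,
    x$positive_label))
  cat(sprintf(
    "  accuracy %.4f | sensitivity %.4f | specificity %.4f | AUC %.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  tuned cost %g, gamma %g (CV accuracy %.4f)\n",
              x$params$cost, x$params$gamma, x$params$cv_accuracy))
  invisible(x)
}
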