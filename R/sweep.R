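## Combination sweep and whole-feature-set baseline: the benchmarking layer
## that produces one evaluation row per (feature-selection pair, community
## detection method).

default_fs_pairs <- function() {
  list(c("svm_sqrt_rfe", "ig"), c("svm_sqrt_rfe", "cs"),
       c("svm_sqrt_rfe", "rf"), c("ig", "cs"), c("ig", "rf"), c("cs", "rf"))
}

fs_label <- function(methods) {
  toupper(paste(methods, collapse = "+"))
}

#' Sweep feature-selection and community-detection combinations
#'
#' Runs the full pipeline for every combination of a feature-selection pair
#' and a community detection method, evaluates each on the test split, and
#' returns one row per combination in the order given. Each unique
#' feature-selection method is scored exactly once (with the same derived
#' seed a standalone [snfs()] call would use) and the ranking is shared
#' across combinations, so removing a combination from the sweep never
#' changes another combination's results. A failing combination is recorded
#' with `NA` metrics and a warning, and the sweep continues.
#'
#' @param train,test [expression_dataset()] objects over the same genes.
#' @param fs_pairs list of character vectors of feature-selection methods;
#'   defaults to all six pairs of `cs`, `ig`, `rf`, `svm_sqrt_rfe`.
#' @param cd_methods community detection methods to cross with.
#' @param positive_label forwarded to [snfs_evaluate()].
#' @param seed master seed fanned out per stage and combination.
#' @param ... further arguments to [snfs()] (percentages, k values, epsilon,
#'   ...).
#' @return data.frame with columns `FS`, `CD`, `CN` (community count),
#'   `Acc`, `Sens`, `Spe`, `AUC`, `FN` (biomarker count); attribute
#'   `details` holds per-row tuned hyperparameters and any error messages.
#' @export
snfs_sweep <- function(train, test,
                       fs_pairs = default_fs_pairs(),
                       cd_methods = c("louvain", "walktrap", "infomap"),
                       positive_label = NULL, seed = 1L, ...) {
  train <- as_expr_dataset(train)
  test <- as_expr_dataset(test)
  dots <- list(...)
  methods <- unique(unlist(fs_pairs))

  rankings <- list()
  for (m in methods) {
    rankings[[m]] <- score_method(
      m, train,
      n_bins = dots$n_bins %||% 10L,
      rf_trees = dots$rf_trees %||% 500L,
      svm_cost = dots$svm_cost %||% 1,
      seed = derive_seed(seed, "rank", m))
  }

  grid <- expand.grid(cd = cd_methods,
                      pair = seq_along(fs_pairs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  details <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pair <- fs_pairs[[grid$pair[i]]]
    cd <- grid$cd[i]
    res <- tryCatch({
      fit <- do.call(snfs, c(list(x = train, fs_methods = pair,
                                  cd_method = cd, seed = seed,
                                  rankings = rankings), dots))
      rep <- snfs_evaluate(fit, test, positive_label)
      details[[i]] <- list(params = rep$params,
                           per_community = fit$biomarkers$per_community)
      data.frame(FS = fs_label(pair), CD = cd,
                 CN = fit$partition$n_communities,
                 Acc = rep$accuracy, Sens = rep$sensitivity,
                 Spe = rep$specificity, AUC = rep$auc,
                 FN = rep$n_features, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("combination ", fs_label(pair), " / ", cd, " failed: ",
              conditionMessage(e), call. = FALSE)
      details[[i]] <<- list(error = conditionMessage(e))
      data.frame(FS = fs_label(pair), CD = cd, CN = NA_integer_,
                 Acc = NA_real_, Sens = NA_real_, Spe = NA_real_,
                 AUC = NA_real_, FN = NA_integer_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  attr(out, "seed") <- seed
  out
}

#' Whole-feature-set baseline
#'
#' Tunes and evaluates the RBF SVM on every gene, with no selection — the
#' reference SNFS is compared against.
#'
#' @inheritParams snfs_sweep
#' @param ... forwarded to [evaluate_classifier()] (grids, folds).
#' @return one-row data.frame in the same shape as [snfs_sweep()] output.
#' @export
snfs_baseline <- function(train, test, positive_label = NULL, seed = 1L,
                          ...) {
  train <- as_expr_dataset(train)
  test <- as_expr_dataset(test)
  rep <- evaluate_classifier(train, test, feature_subset = NULL,
                             positive_label = positive_label,
                             seed = derive_seed(seed, "svm"), ...)
  out <- data.frame(FS = "NONE (ALL GENES)", CD = NA_character_,
                    CN = NA_integer_, Acc = rep$accuracy,
                    Sens = rep$sensitivity, Spe = rep$specificity,
                    AUC = rep$auc, FN = rep$n_features,
                    stringsAsFactors = FALSE)
  attr(out, "details") <- list(list(params = rep$params))
  out
}

#' Write a sweep results table
#'
#' TSV with the `FS, CD, CN, Acc, Sens, Spe, AUC, FN` columns plus a JSON
#' sidecar carrying the seed and per-row tuned hyperparameters.
#'
#' @param results data.frame from [snfs_sweep()] or [snfs_baseline()].
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_results_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(seed = attr(results, "seed"),
                  details = attr(results, "details"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run a full configured pipeline
#'
#' Thin orchestration over [simulate_expression()] / [read_expression_tsv()],
#' [snfs_sweep()] and [snfs_baseline()], used by the command-line wrapper.
#' The config is a plain named list (e.g. parsed from YAML): either a
#' `simulation` sub-list of [sim_config()] arguments or `train_matrix` /
#' `train_labels` / `test_matrix` / `test_labels` paths; optional entries
#' `fs_pairs`, `cd_methods`, `candidate_percent`, `biomarker_percent`,
#' `k_values`, `epsilon`, `edge_threshold`, `baseline` (logical), `seed`,
#' `output_dir`.
#'
#' @param config named list as described above.
#' @return the combined results data.frame, invisibly if written to disk.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  if (!is.null(config$simulation)) {
    sim <- simulate_expression(do.call(sim_config, c(config$simulation,
                                                     list(seed = seed))))
    train <- sim$train; test <- sim$test
  } else {
    train <- read_expression_tsv(config$train_matrix, config$train_labels,
                                 isTRUE(config$samples_in_rows))
    test <- read_expression_tsv(config$test_matrix, config$test_labels,
                                isTRUE(config$samples_in_rows))
  }
  args <- list(train = train, test = test, seed = seed)
  for (key in c("candidate_percent", "biomarker_percent", "k_values",
                "epsilon", "edge_threshold", "n_bins", "rf_trees",
                "svm_cost", "positive_label"))
    args[[key]] <- config[[key]]
  if (!is.null(config$fs_pairs))
    args$fs_pairs <- lapply(config$fs_pairs, as.character)
  if (!is.null(config$cd_methods)) args$cd_methods <- config$cd_methods
  results <- do.call(snfs_sweep, args)
  if (isTRUE(config$baseline)) {
    base <- snfs_baseline(train, test, positive_label =
                            config$positive_label, seed = seed)
    results <- rbind(results, base)
    attr(results, "seed") <- seed
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(results,
                        file.path(config$output_dir, "results.tsv"))
    return(invisible(results))
  }
  results
}
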