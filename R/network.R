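## Stage 2: class-mean reduction and the k-means co-occurrence network.

#' Class-mean profile of candidate genes
#'
#' Reduces each candidate gene to its mean expression per class on the
#' training samples, the low-dimensional representation clustered in the
#' network stage. With two classes each gene becomes a point in the plane.
#'
#' @param train an [expression_dataset()] (or matrix plus `labels`).
#' @param candidates a `candidate_set` or character vector of gene ids.
#' @param labels class labels when `train` is a plain matrix.
#' @return numeric matrix, candidate genes x classes.
#' @export
class_mean_profile <- function(train, candidates, labels = NULL) {
  train <- assert_two_classes(as_expr_dataset(train, labels))
  ids <- if (inherits(candidates, "candidate_set")) candidates$gene_ids
         else as.character(candidates)
  missing <- setdiff(ids, rownames(train$values))
  if (length(missing))
    stop("candidate genes absent from the dataset: ",
         paste(head(missing, 5), collapse = ", "))
  if (any(tabulate(train$labels) == 0L))
    stop("every class needs at least one training sample")
  x <- train$values[ids, , drop = FALSE]
  profile <- vapply(levels(train$labels),
                    function(cl) rowMeans(x[, train$labels == cl,
                                            drop = FALSE]),
                    numeric(length(ids)))
  dimnames(profile) <- list(ids, levels(train$labels))
  profile
}

# k-means++ seeding: spread initial centers by sampling points with
# probability proportional to squared distance from the nearest chosen
# center. Lloyd refinement is delegated to stats::kmeans.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

# One seeded k-means run: best of `restarts` k-means++ initializations by
# total within-cluster sum of squares. k-means++ never seeds two centers on
# coincident points (selection probability is proportional to squared
# distance from the chosen set), so initial centers are always distinct when
# the data admit k distinct points; with fewer distinct points than k the
# clustering degenerates to grouping by identity.
kmeans_run <- function(x, k, restarts) {
  ux <- unique(x)
  if (nrow(ux) <= k)
    return(match(apply(x, 1L, paste, collapse = "\r"),
                 apply(ux, 1L, paste, collapse = "\r")))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_centers(x, k)
    km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = init,
                                                  iter.max = 50L)),
                   error = function(e) NULL)
    if (!is.null(km) &&
        (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart at k = ", k)
  best$cluster
}

#' Co-occurrence adjacency over candidate genes
#'
#' Runs k-means on the gene rows of the class-mean profile once per entry of
#' `k_values` (k-means++ initialization, `restarts` restarts per run,
#' Euclidean distance on the raw profile) and counts, for every gene pair,
#' in how many runs the two genes share a cluster. The result is a symmetric
#' integer matrix with zero diagonal and entries between 0 and
#' `length(k_values)`.
#'
#' @param profile matrix from [class_mean_profile()] (genes x classes).
#' @param k_values cluster counts, one k-means run per entry (repeats
#'   allowed to increase the repetition number).
#' @param restarts k-means++ restarts per run; the best fit by total
#'   within-cluster sum of squares is kept.
#' @param seed RNG seed for initialization.
#' @return a `cooccurrence` object: list with integer `matrix`,
#'   `k_values`, and `repetitions` (the maximum possible entry).
#' @export
cooccurrence_adjacency <- function(profile, k_values = c(3L, 4L, 5L),
                                   restarts = 10L, seed = 1L) {
  profile <- as.matrix(profile)
  p <- nrow(profile)
  if (any(k_values < 2L)) stop("every k must be at least 2")
  if (any(k_values > p)) stop("k exceeds the number of candidate genes (",
                              p, ")")
  adj <- matrix(0L, p, p, dimnames = list(rownames(profile),
                                          rownames(profile)))
  with_seed(seed, {
    for (k in k_values) {
      cl <- kmeans_run(profile, k, restarts)
      for (g in unique(cl)) {
        idx <- which(cl == g)
        adj[idx, idx] <- adj[idx, idx] + 1L
      }
    }
  })
  diag(adj) <- 0L
  structure(list(matrix = adj, k_values = as.integer(k_values),
                 repetitions = length(k_values)),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("co-occurrence adjacency:", nrow(x$matrix), "genes,",
      x$repetitions, "clustering runs (k =",
      paste(x$k_values, collapse = ", "), ")\n")
  cat("nonzero entries:", sum(x$matrix > 0) / 2, "pairs\n")
  invisible(x)
}

#' Write / read a co-occurrence adjacency as an edge list
#'
#' TSV with columns `gene_i`, `gene_j`, `weight` for every pair with
#' positive weight (each undirected pair once). The reader rebuilds the full
#' symmetric matrix; genes with no edges are preserved through the
#' `gene_ids` header comment.
#'
#' @param adj a `cooccurrence` object.
#' @param path output/input file.
#' @export
write_adjacency_tsv <- function(adj, path) {
  stopifnot(inherits(adj, "cooccurrence"))
  m <- adj$matrix
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# genes: ", paste(rownames(m), collapse = ",")),
               paste0("# k_values: ", paste(adj$k_values, collapse = ","))),
             con)
  write.table(data.frame(gene_i = rownames(m)[idx[, 1]],
                         gene_j = colnames(m)[idx[, 2]],
                         weight = m[idx]),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @export
read_adjacency_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  genes <- strsplit(sub("^# genes: ", "", hdr[1]), ",")[[1]]
  k_values <- as.integer(strsplit(sub("^# k_values: ", "", hdr[2]),
                                  ",")[[1]])
  df <- read.delim(path, skip = 2L, stringsAsFactors = FALSE)
  m <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  i <- match(df$gene_i, genes); j <- match(df$gene_j, genes)
  m[cbind(i, j)] <- as.integer(df$weight)
  m[cbind(j, i)] <- as.integer(df$weight)
  structure(list(matrix = m, k_values = k_values,
                 repetitions = length(k_values)),
            class = "cooccurrence")
}
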