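#' Construct an expression dataset
#'
#' Bundles a genes-by-samples numeric matrix with one class label per sample.
#' This is the carrier object for every pipeline stage; labels must take
#' exactly two distinct values for a feature-selection run, which is checked
#' at fit time rather than here so partially built objects remain usable.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers when `gene_ids` /
#'   `sample_ids` are not given.
#' @param labels class label per sample (coerced to factor), recycled names
#'   are not allowed: length must equal `ncol(values)`.
#' @param gene_ids,sample_ids optional identifier vectors; must be unique.
#' @return an object of class `expr_dataset`: a list with elements `values`
#'   (matrix with dimnames set) and `labels` (named factor).
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' d <- expression_dataset(x, labels = c(1, 1, 1, 2, 2))
#' dim(d$values)
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL,
                               sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression values contain missing entries")
  gene_ids <- gene_ids %||% rownames(values) %||%
    sprintf("g%0*d", nchar(nrow(values)), seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||%
    sprintf("s%0*d", nchar(ncol(values)), seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (length(labels) != ncol(values))
    stop("need one label per sample (", ncol(values), "), got ",
         length(labels))
  labels <- factor(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  dimnames(values) <- list(gene_ids, sample_ids)
  names(labels) <- sample_ids
  structure(list(values = values, labels = labels), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expression dataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("classes:", paste(sprintf("%s (n=%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

# Internal: accept either an expr_dataset or matrix + labels.
as_expr_dataset <- function(x, labels = NULL) {
  if (inherits(x, "expr_dataset")) return(x)
  if (is.null(labels)) stop("labels are required when `x` is a plain matrix")
  expression_dataset(x, labels)
}

assert_two_classes <- function(data) {
  if (nlevels(droplevels(data$labels)) != 2L)
    stop("exactly two classes are required, found ",
         nlevels(droplevels(data$labels)))
  invisible(data)
}

#' Write / read an expression dataset as delimited text
#'
#' The matrix file is TSV with genes as rows: first column `gene_id`, then
#' one column per sample named by its identifier. Labels go to a companion
#' two-column TSV (`sample_id`, `class`). `read_expression_tsv()` accepts
#' the same dialect, plus a transposed samples-by-genes layout via
#' `samples_in_rows = TRUE`.
#'
#' @param data an `expr_dataset`.
#' @param prefix output path prefix; writes `<prefix>_expr.tsv` and
#'   `<prefix>_labels.tsv`.
#' @return `write_expression_tsv()` returns the two paths invisibly;
#'   `read_expression_tsv()` returns an `expr_dataset`.
#' @export
write_expression_tsv <- function(data, prefix) {
  stopifnot(inherits(data, "expr_dataset"))
  mat_path <- paste0(prefix, "_expr.tsv")
  lab_path <- paste0(prefix, "_labels.tsv")
  df <- data.frame(gene_id = rownames(data$values), data$values,
                   check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(data$labels),
                         class = as.character(data$labels)),
              lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mat_path, labels = lab_path))
}

#' @param matrix_file,label_file paths as written by `write_expression_tsv()`.
#' @param samples_in_rows if `TRUE` the matrix file holds samples as rows and
#'   genes as columns (first column the sample identifier).
#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_file, label_file,
                                samples_in_rows = FALSE) {
  df <- read.delim(matrix_file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  if (samples_in_rows) {
    m <- t(m)
    colnames(m) <- ids
  } else {
    rownames(m) <- ids
  }
  lab <- read.delim(label_file, stringsAsFactors = FALSE)
  idx <- match(colnames(m), as.character(lab[[1]]))
  if (anyNA(idx)) stop("label file is missing samples: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  expression_dataset(m, labels = lab[[2]][idx])
}
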