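#' Simulation configuration for blocked-covariance expression data
#'
#' The generator follows the two-group dependency design used to benchmark
#' hybrid feature selection: genes come in independent blocks, genes within a
#' block follow a multivariate normal with AR-style covariance
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}}, the sign of \eqn{\rho} alternates across
#' block groups (the first `n_positive_blocks` blocks positive, the rest
#' negative), and class 2 receives an additive mean shift on the first
#' `n_shifted_genes` genes. Defaults reproduce the benchmark conditions:
#' 10,000 genes in 100 blocks of 100, a +0.5 shift on the first 200 genes
#' (the first two blocks), 200 training and 600 test samples, balanced
#' classes.
#'
#' @param n_genes total number of genes.
#' @param n_blocks number of independent blocks (`n_blocks * block_size`
#'   must equal `n_genes`).
#' @param block_size genes per block.
#' @param rho within-block correlation magnitude, in `[0, 1)`.
#' @param n_positive_blocks how many leading blocks use `+rho`; the rest use
#'   `-rho`. Default: half the blocks (rounded up).
#' @param shift additive offset applied to class-2 samples.
#' @param n_shifted_genes number of leading genes receiving the shift.
#' @param n_train,n_test sample counts of the two independently drawn splits.
#' @param class_balance fraction of samples in class 1.
#' @param seed RNG seed driving the whole draw.
#' @return a validated list of class `snfs_sim_config`.
#' @seealso [simulate_expression()]
#' @export
sim_config <- function(n_genes = 10000L, n_blocks = 100L, block_size = 100L,
                       rho = 0.6, n_positive_blocks = NULL, shift = 0.5,
                       n_shifted_genes = 200L, n_train = 200L, n_test = 600L,
                       class_balance = 0.5, seed = 1L) {
  n_positive_blocks <- n_positive_blocks %||% ceiling(n_blocks / 2)
  cfg <- list(n_genes = as.integer(n_genes), n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size), rho = rho,
              n_positive_blocks = as.integer(n_positive_blocks),
              shift = shift, n_shifted_genes = as.integer(n_shifted_genes),
              n_train = as.integer(n_train), n_test = as.integer(n_test),
              class_balance = class_balance, seed = as.integer(seed))
  if (cfg$n_blocks * cfg$block_size != cfg$n_genes)
    stop("n_blocks * block_size must equal n_genes")
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop("rho must lie in [0, 1); use n_positive_blocks for the sign pattern")
  if (cfg$n_shifted_genes > cfg$n_genes)
    stop("n_shifted_genes exceeds n_genes")
  if (cfg$n_positive_blocks > cfg$n_blocks)
    stop("n_positive_blocks exceeds n_blocks")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    stop("class_balance must lie strictly between 0 and 1")
  if (cfg$n_train < 2L || cfg$n_test < 2L)
    stop("both splits need at least 2 samples")
  structure(cfg, class = "snfs_sim_config")
}

#' Within-block covariance matrix
#'
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}}: unit diagonal, symmetric, positive
#' definite for \eqn{|\rho| < 1}. `rho` is signed here; negative values give
#' the alternating-sign covariance used by the second block group.
#'
#' @param size matrix order (genes per block).
#' @param rho signed correlation, `abs(rho) < 1`.
#' @return a `size` x `size` numeric matrix.
#' @examples
#' block_covariance(3, 0.9)
#' @export
block_covariance <- function(size, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1 for a valid covariance")
  if (size < 1) stop("size must be >= 1")
  rho^abs(outer(seq_len(size), seq_len(size), "-"))
}

#' Symmetric (spectral) matrix square root
#'
#' Returns the unique symmetric positive-definite `S` with `S %*% S` equal to
#' the input, via eigendecomposition. Chosen over a Cholesky factor because
#' it is itself symmetric, so `S %*% t(S) == S %*% S` and either reading of
#' "multiply by the square root of the covariance" gives the same draw.
#'
#' @param sigma symmetric positive-definite matrix.
#' @param tol relative eigenvalue tolerance below which the matrix is
#'   rejected as not positive definite.
#' @return symmetric matrix `S` of the same order.
#' @export
sym_matrix_sqrt <- function(sigma, tol = 1e-10) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(unname(sigma), tol = 1e-8))
    stop("matrix is not symmetric")
  es <- eigen(sigma, symmetric = TRUE)
  if (any(es$values < tol * max(es$values)))
    stop("matrix is not positive definite: smallest eigenvalue ",
         format(min(es$values)))
  es$vectors %*% (sqrt(es$values) * t(es$vectors))
}

#' Generate a synthetic two-class expression study
#'
#' Draws independent training and test splits under the blocked-covariance
#' design described in [sim_config()]. For each block, i.i.d. standard-normal
#' gene vectors are multiplied by the block's symmetric covariance square
#' root; the first `n_positive_blocks` blocks use `+rho`, the remainder
#' `-rho`, and blocks are mutually independent. After the transformation the
#' mean `shift` is added to the first `n_shifted_genes` genes of class-2
#' samples only. The RNG stream order is fixed and documented — training
#' split first, then test split, each filled block by block — so a given
#' seed always reproduces the same pair of datasets.
#'
#' @param config an `snfs_sim_config`, or arguments forwarded to
#'   [sim_config()] via `...`.
#' @param ... overrides passed to [sim_config()] when `config` is missing.
#' @return list with elements `train` and `test` (both [expression_dataset()]
#'   objects with class labels `"1"`/`"2"`) and `config`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 60, n_blocks = 6,
#'   block_size = 10, n_shifted_genes = 10, n_positive_blocks = 3,
#'   n_train = 20, n_test = 20, seed = 7))
#' sim$train
#' @export
simulate_expression <- function(config = NULL, ...) {
  cfg <- config %||% sim_config(...)
  stopifnot(inherits(cfg, "snfs_sim_config"))
  roots <- list(
    pos = sym_matrix_sqrt(block_covariance(cfg$block_size, cfg$rho)),
    neg = sym_matrix_sqrt(block_covariance(cfg$block_size, -cfg$rho)))
  gene_ids <- sprintf("g%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))

  draw_split <- function(n, prefix) {
    n1 <- round(cfg$class_balance * n)
    if (n1 < 1 || n1 > n - 1) stop("class_balance leaves a class empty")
    labels <- rep(c("1", "2"), c(n1, n - n1))
    x <- matrix(0, nrow = cfg$n_genes, ncol = n)
    for (b in seq_len(cfg$n_blocks)) {
      rows <- ((b - 1L) * cfg$block_size + 1L):(b * cfg$block_size)
      root <- if (b <= cfg$n_positive_blocks) roots$pos else roots$neg
      z <- matrix(rnorm(cfg$block_size * n), nrow = cfg$block_size, ncol = n)
      x[rows, ] <- root %*% z
    }
    if (cfg$n_shifted_genes > 0)
      x[seq_len(cfg$n_shifted_genes), labels == "2"] <-
        x[seq_len(cfg$n_shifted_genes), labels == "2"] + cfg$shift
    expression_dataset(x, labels, gene_ids = gene_ids,
                       sample_ids = sprintf("%s%0*d", prefix, nchar(n),
                                            seq_len(n)))
  }

  with_seed(cfg$seed, {
    train <- draw_split(cfg$n_train, "train_")
    test <- draw_split(cfg$n_test, "test_")
    list(train = train, test = test, config = cfg)
  })
}
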