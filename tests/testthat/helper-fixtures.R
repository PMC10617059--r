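# Shared fixtures, all generated in code.

# Small blocked-covariance study: 500 genes in 10 blocks of 50, the first
# 50 genes shifted, 60 train / 100 test samples.
small_sim <- function(seed = 11, rho = 0.6, ...) {
  simulate_expression(sim_config(
    n_genes = 500L, n_blocks = 10L, block_size = 50L, rho = rho,
    n_positive_blocks = 5L, n_shifted_genes = 50L, n_train = 60L,
    n_test = 100L, seed = seed, ...))
}

# Tiny two-class dataset where gene "gA" separates the classes perfectly,
# "gB" is constant, the rest standard-normal noise.
toy_separable <- function(n_per_class = 10, n_noise = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("1", "2"), each = n_per_class)
  values <- rbind(ifelse(labels == "2", 1, 0), rep(3, n))
  if (n_noise > 0) values <- rbind(values, matrix(rnorm(n_noise * n),
                                                  n_noise, n))
  rownames(values) <- c("gA", "gB",
                        if (n_noise > 0) paste0("gN", seq_len(n_noise)))
  expression_dataset(values, labels)
}

# Class-mean profile with 3 well-separated pairs of identical genes.
paired_profile <- function() {
  m <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(0, 20), c(0, 20))
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- c("1", "2")
  m
}

# Trapezoidal ROC integration: the independent oracle for the pairwise AUC.
auc_trapezoid <- function(scores, labels, positive) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == positive] >= t),
                numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels != positive] >= t),
                numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Brute-force pairwise AUC with half-credit for ties.
auc_pairwise_bruteforce <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
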