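# Stage 3: graph construction, community detection, corrected degree of
# domesticity, per-community selection.

# enumerate all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (id in seq_len(maxid + 1L))
      recurse(c(prefix, id), max(maxid, id))
  }
  recurse(1L, 1L)
  out
}

# weighted Newman modularity computed from scratch
modularity_oracle <- function(adj, cl) {
  two_m <- sum(adj)
  k <- rowSums(adj)
  b <- adj - outer(k, k) / two_m
  sum(b[outer(cl, cl, "==")]) / two_m
}

two_cliques <- function(n_clique = 5, w = 3L) {
  n <- 2 * n_clique
  m <- matrix(0L, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  m[1:n_clique, 1:n_clique] <- w
  m[(n_clique + 1):n, (n_clique + 1):n] <- w
  diag(m) <- 0L
  # one weak bridge so the graph is connected and the split is non-trivial
  m[1, n_clique + 1] <- m[n_clique + 1, 1] <- 1L
  m
}

test_that("edge thresholding keeps exactly the entries at or above it", {
  prof <- paired_profile()
  adj <- cooccurrence_adjacency(prof, k_values = c(3, 3, 3), seed = 2)
  g1 <- build_gene_graph(adj, edge_threshold = 1)
  expect_equal(igraph::ecount(g1), 3)
  expect_equal(igraph::E(g1)$weight, rep(3, 3))
  g_empty <- build_gene_graph(adj, edge_threshold = 4)  # R + 1
  expect_equal(igraph::ecount(g_empty), 0)
  expect_equal(igraph::vcount(g_empty), 6)
  # hand-built 4x4 with entries {0,1,2,3}: threshold 2 keeps the >= 2 cells
  m <- rbind(c(0, 1, 2, 0), c(1, 0, 3, 0), c(2, 3, 0, 1), c(0, 0, 1, 0))
  dimnames(m) <- list(letters[1:4], letters[1:4])
  g2 <- build_gene_graph(m, edge_threshold = 2)
  el <- igraph::as_edgelist(g2)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el[, 1], el[, 2]), c("a c", "b c"))
  expect_error(build_gene_graph(m, edge_threshold = 0), "at least 1")
})

test_that("all three methods recover two cliques, matching the exhaustive
          modularity optimum", {
  adj <- two_cliques(5)
  g <- build_gene_graph(adj)
  truth <- rep(1:2, each = 5)
  # independent oracle: best partition of 10 nodes by brute force
  parts <- all_partitions(10)
  qs <- vapply(parts, function(cl) modularity_oracle(adj, cl), numeric(1))
  best <- parts[[which.max(qs)]]
  expect_equal(best, truth)
  for (method in c("louvain", "walktrap", "infomap")) {
    part <- detect_communities(g, method, seed = 1)
    expect_equal(part$n_communities, 2)
    expect_equal(unname(part$membership), truth, label = method)
    expect_equal(modularity_oracle(adj, part$membership), max(qs),
                 tolerance = 1e-12)
  }
})

test_that("community detection is deterministic given the seed and handles
          isolated and singleton graphs", {
  sim <- small_sim(seed = 6)
  fitm <- class_mean_profile(sim$train, rownames(sim$train$values)[1:80])
  adj <- cooccurrence_adjacency(fitm, seed = 5)
  g <- build_gene_graph(adj, edge_threshold = 3)  # sparse: expect isolates
  for (method in c("louvain", "infomap")) {
    p1 <- detect_communities(g, method, seed = 9)
    p2 <- detect_communities(g, method, seed = 9)
    expect_identical(p1$membership, p2$membership)
  }
  # isolated vertices become singleton communities
  iso <- igraph::degree(g) == 0
  if (any(iso)) {
    p <- detect_communities(g, "louvain", seed = 9)
    sizes <- table(p$membership)
    expect_true(all(sizes[as.character(p$membership[iso])] == 1))
  }
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "only"
  expect_equal(detect_communities(single, "walktrap")$n_communities, 1)
  expect_error(detect_communities(g, "leiden"), "arg")
})

test_that("corrected degree of domesticity follows the epsilon-corrected
          ratio", {
  # star-like toy: node h has 6 in-community and 3 out-of-community edges
  el <- rbind(cbind("h", paste0("in", 1:6)), cbind("h", paste0("out", 1:3)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  memb <- stats::setNames(c(1, rep(1, 6), rep(2, 3)), c("h", paste0("in", 1:6),
                                                 paste0("out", 1:3)))
  part <- structure(list(membership = memb, method = "manual",
                         n_communities = 2), class = "community_partition")
  met <- domesticity_metrics(g, part, epsilon = 1e-6)
  h <- met[met$gene == "h", ]
  expect_equal(h$z_in, 6)
  expect_equal(h$z_out, 3)
  expect_equal(h$z_d, 2, tolerance = 1e-6)
  expect_equal(h$degree, 9)
  expect_equal(h$coverage, 2 / 3)
  # node with no outside edges: finite, huge, ordered by z_in
  in1 <- met[met$gene == "in1", ]           # 1 edge, inside own community
  expect_equal(in1$z_in, 1)
  expect_equal(in1$z_out, 0)
  expect_equal(in1$z_d, (1 + 1e-6) / 1e-6)
  expect_gt(in1$z_d, h$z_d)
  # direct evaluation of the motivating case z_in = 5, z_out = 0
  expect_equal((5 + 1e-6) / (0 + 1e-6), 5000001, tolerance = 1e-9)
  expect_error(domesticity_metrics(g, part, epsilon = 0), "positive")
})

test_that("z_in + z_out equals degree and intra-edge double counting holds", {
  sim <- small_sim(seed = 13)
  fitm <- class_mean_profile(sim$train, rownames(sim$train$values)[1:100])
  adj <- cooccurrence_adjacency(fitm, seed = 4)
  g <- build_gene_graph(adj)
  part <- detect_communities(g, "louvain", seed = 4)
  met <- domesticity_metrics(g, part)
  expect_equal(met$z_in + met$z_out, met$degree)
  expect_equal(met$degree,
               unname(igraph::degree(g)[match(met$gene,
                                              igraph::V(g)$name)]))
  memb <- part$membership[igraph::V(g)$name]
  el <- igraph::as_edgelist(g)
  intra <- sum(memb[el[, 1]] == memb[el[, 2]])
  expect_equal(sum(met$z_in), 2 * intra)
  expect_equal(met$weighted_degree,
               unname(igraph::strength(g)[match(met$gene,
                                                igraph::V(g)$name)]))
  # isolated node gets z_d = 1 (epsilon / epsilon)
  if (any(met$degree == 0)) expect_true(all(met$z_d[met$degree == 0] == 1))
})

test_that("per-community selection takes the ceiling of the percentage", {
  mk_metrics <- function(sizes) {
    genes <- sprintf("g%03d", seq_len(sum(sizes)))
    comm <- rep(seq_along(sizes), sizes)
    structure(data.frame(gene = genes, community = comm,
                         z_in = rev(seq_along(genes)), z_out = 1,
                         z_d = rev(seq_along(genes)),
                         degree = 1, weighted_degree = 1,
                         intra_centrality = 0, out_centrality = 0,
                         coverage = 0),
              class = c("node_metrics", "data.frame"))
  }
  one <- select_biomarkers(mk_metrics(10), 0.10)
  expect_length(one$gene_ids, 1)
  expect_equal(one$gene_ids, "g001")          # max z_d in the community
  eleven <- select_biomarkers(mk_metrics(11), 0.10)
  expect_length(eleven$gene_ids, 2)
  multi <- select_biomarkers(mk_metrics(c(195, 183, 122)), 0.10)
  expect_equal(unname(multi$per_community), c(20, 19, 13))
  expect_length(multi$gene_ids, 52)
  expect_false(anyDuplicated(multi$gene_ids) > 0)
  expect_error(select_biomarkers(mk_metrics(10), 0), "percent")
})

test_that("graph and metrics exports are written and re-readable", {
  adj <- two_cliques(4)
  g <- build_gene_graph(adj)
  part <- detect_communities(g, "louvain", seed = 1)
  met <- domesticity_metrics(g, part)
  bio <- select_biomarkers(met, 0.25)
  prefix <- tempfile()
  paths <- write_graph_exports(g, met, bio, prefix)
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths["graph"], format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  tab <- read.delim(paths["metrics"])
  expect_equal(sum(tab$selected), length(bio$gene_ids))
})
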