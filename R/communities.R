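## Stage 3: gene graph, community detection, corrected degree of
## domesticity, biomarker selection.

#' Build the weighted gene graph
#'
#' Converts a co-occurrence adjacency into an undirected weighted graph. An
#' edge is present wherever the co-occurrence count reaches
#' `edge_threshold` and carries that count as its weight. Genes that end up
#' without edges stay in the graph as isolated vertices (they become
#' singleton communities downstream).
#'
#' @param adj a `cooccurrence` object or a symmetric non-negative integer
#'   matrix with named rows.
#' @param edge_threshold minimum co-occurrence count for an edge, >= 1.
#' @return an [igraph::graph] with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
build_gene_graph <- function(adj, edge_threshold = 1L) {
  m <- if (inherits(adj, "cooccurrence")) adj$matrix else as.matrix(adj)
  if (edge_threshold < 1L) stop("edge_threshold must be at least 1")
  m[m < edge_threshold] <- 0L
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Detect communities in the gene graph
#'
#' Weighted community detection by Louvain (modularity optimization),
#' Walktrap (random-walk agglomeration, 4 steps) or Infomap (map-equation
#' compression). Isolated vertices come out as singleton communities.
#' Louvain and Infomap are stochastic; the supplied seed makes them
#' reproducible.
#'
#' @param graph graph from [build_gene_graph()].
#' @param method `"louvain"`, `"walktrap"` or `"infomap"`.
#' @param seed RNG seed for the stochastic methods.
#' @return a `community_partition`: list with `membership` (named integer
#'   vector, community ids dense from 1 in order of first appearance),
#'   `method` and `n_communities`.
#' @export
detect_communities <- function(graph, method = c("louvain", "walktrap",
                                                 "infomap"), seed = 1L) {
  method <- match.arg(method)
  comm <- with_seed(seed, switch(
    method,
    louvain = igraph::cluster_louvain(graph),
    walktrap = igraph::cluster_walktrap(graph, steps = 4L),
    infomap = igraph::cluster_infomap(graph)))
  memb <- igraph::membership(comm)
  dense <- as.integer(factor(as.integer(memb),
                             levels = unique(as.integer(memb))))
  names(dense) <- igraph::V(graph)$name
  structure(list(membership = dense, method = method,
                 n_communities = length(unique(dense))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat("community partition (", x$method, "): ", x$n_communities,
      " communities over ", length(x$membership), " genes\n", sep = "")
  cat("sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Corrected degree of domesticity and companion node metrics
#'
#' For every node, counts its unweighted edges to nodes of its own community
#' (`z_in`) and to nodes of other communities (`z_out`) and computes the
#' corrected degree of domesticity
#' \deqn{z_d = (z_{in} + \epsilon) / (z_{out} + \epsilon).}
#' The epsilon correction keeps \eqn{z_d} finite for nodes with no edges
#' outside their community — where the raw ratio \eqn{z_{in}/z_{out}} is
#' undefined — and, for any \eqn{\epsilon < 1/\mathrm{degree}_{max}^2},
#' ranks all such nodes above every node with an outside edge while still
#' ordering them among themselves by `z_in`. An isolated node gets
#' \eqn{z_d = \epsilon/\epsilon = 1}.
#'
#' Companion metrics: unweighted `degree` (`z_in + z_out`), `weighted_degree`
#' (sum of incident edge weights), `intra_centrality` (`z_in` normalized by
#' community size minus 1), `out_centrality` (`z_out` normalized by the
#' number of nodes outside the community) and `coverage`
#' (`z_in / (z_in + z_out)`, 0 for isolated nodes). Only `z_d` drives
#' biomarker selection.
#'
#' @param graph graph from [build_gene_graph()].
#' @param partition a `community_partition` over the same vertices.
#' @param epsilon positive correction constant (default `1e-6`).
#' @return a `node_metrics` data.frame with one row per gene: `gene`,
#'   `community`, `z_in`, `z_out`, `z_d`, `degree`, `weighted_degree`,
#'   `intra_centrality`, `out_centrality`, `coverage`.
#' @export
domesticity_metrics <- function(graph, partition, epsilon = 1e-6) {
  if (epsilon <= 0) stop("epsilon must be strictly positive")
  stopifnot(inherits(partition, "community_partition"))
  memb <- partition$membership
  vnames <- igraph::V(graph)$name
  if (!identical(sort(vnames), sort(names(memb))))
    stop("partition does not cover the graph's vertices")
  memb <- memb[vnames]
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  n <- length(vnames)
  z_in <- z_out <- wdeg <- numeric(n)
  names(z_in) <- names(z_out) <- names(wdeg) <- vnames
  if (nrow(el)) {
    same <- memb[el[, 1]] == memb[el[, 2]]
    for (side in 1:2) {
      t_in <- tapply(same, el[, side], sum)
      t_all <- tapply(rep(1, nrow(el)), el[, side], sum)
      t_w <- tapply(w, el[, side], sum)
      z_in[names(t_in)] <- z_in[names(t_in)] + t_in
      z_out[names(t_all)] <- z_out[names(t_all)] + t_all
      wdeg[names(t_w)] <- wdeg[names(t_w)] + t_w
    }
    z_out <- z_out - z_in
  }
  csize <- table(memb)
  size_own <- as.numeric(csize[as.character(memb)])
  deg <- z_in + z_out
  out <- data.frame(
    gene = vnames,
    community = as.integer(memb),
    z_in = as.numeric(z_in),
    z_out = as.numeric(z_out),
    z_d = (z_in + epsilon) / (z_out + epsilon),
    degree = as.numeric(deg),
    weighted_degree = as.numeric(wdeg),
    intra_centrality = ifelse(size_own > 1, z_in / (size_own - 1), 0),
    out_centrality = ifelse(n > size_own, z_out / (n - size_own), 0),
    coverage = ifelse(deg > 0, z_in / deg, 0),
    row.names = NULL)
  structure(out, class = c("node_metrics", "data.frame"),
            epsilon = epsilon, method = partition$method)
}

#' Select biomarkers per community
#'
#' Within each community, genes are sorted by decreasing corrected degree of
#' domesticity (ties: larger `z_in`, then gene identifier) and the top
#' `ceiling(percent * community size)` genes are selected.
#'
#' @param metrics a `node_metrics` data.frame from [domesticity_metrics()].
#' @param percent per-community selection fraction, in `(0, 1]`.
#' @return a `biomarker_set`: list with `gene_ids`, `per_community` (named
#'   count vector), `percent` and `metric`.
#' @export
select_biomarkers <- function(metrics, percent = 0.10) {
  stopifnot(inherits(metrics, "node_metrics"))
  if (percent <= 0 || percent > 1) stop("percent must lie in (0, 1]")
  picks <- lapply(split(metrics, metrics$community), function(df) {
    df <- df[order(-df$z_d, -df$z_in, df$gene), , drop = FALSE]
    df$gene[seq_len(top_n_by_percent(nrow(df), percent))]
  })
  structure(list(gene_ids = unlist(picks, use.names = FALSE),
                 per_community = vapply(picks, length, integer(1)),
                 percent = percent, metric = "z_d"),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("biomarker set:", length(x$gene_ids), "genes from",
      length(x$per_community), "communities (top",
      sprintf("%.0f%%", 100 * x$percent), "by", x$metric, ")\n")
  cat("per community:", paste(x$per_community, collapse = ", "), "\n")
  invisible(x)
}

#' Export the gene graph and node metrics
#'
#' Writes the graph as GraphML (vertex attribute `community`) and the
#' metrics table (with a `selected` flag) as TSV.
#'
#' @param graph graph from [build_gene_graph()].
#' @param metrics a `node_metrics` data.frame.
#' @param biomarkers optional `biomarker_set` used for the `selected` flag.
#' @param prefix output path prefix; writes `<prefix>_graph.graphml` and
#'   `<prefix>_metrics.tsv`.
#' @export
write_graph_exports <- function(graph, metrics, biomarkers = NULL, prefix) {
  idx <- match(igraph::V(graph)$name, metrics$gene)
  igraph::V(graph)$community <- metrics$community[idx]
  gpath <- paste0(prefix, "_graph.graphml")
  igraph::write_graph(graph, gpath, format = "graphml")
  tab <- as.data.frame(metrics)
  tab$selected <- tab$gene %in% (biomarkers$gene_ids %||% character(0))
  mpath <- paste0(prefix, "_metrics.tsv")
  write.table(tab, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graph = gpath, metrics = mpath))
}
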