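#' Weighted graph-theory measures for connectomes
#'
#' All measures operate on undirected, non-negative, weighted adjacency
#' matrices (connectivity-toolbox conventions). Path-based measures convert
#' weights to traversal lengths by the reciprocal (length = 1/weight;
#' absent edges are unreachable), the standard convention when stronger
#' connections are "shorter". Clustering uses the Onnela geometric-mean
#' form with weights normalized by the graph maximum; local efficiency is
#' the global efficiency of the neighbor-induced subgraph with inherited
#' weights. Shortest-path machinery (Dijkstra, weighted Brandes
#' betweenness) is delegated to igraph; every measure is cross-checked
#' against brute-force enumeration oracles in the test suite.
#'
#' @name graph_metrics
NULL

#' Validate an adjacency matrix as a weighted graph
#'
#' @param mat Square symmetric non-negative matrix, zero diagonal.
#' @return The matrix, invisibly classed \code{"weighted_graph"}.
#' @export
as_weighted_graph <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-10)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(mat < 0)) stop("adjacency must be non-negative", call. = FALSE)
  if (any(diag(mat) != 0)) stop("self-loops are not allowed", call. = FALSE)
  structure(mat, class = c("weighted_graph", class(mat)))
}

#' Convert connection weights to traversal lengths
#'
#' @param weights Non-negative matrix (or vector).
#' @return Elementwise 1/weights; zeros map to Inf (unreachable).
#' @export
to_lengths <- function(weights) {
  out <- ifelse(weights > 0, 1 / weights, Inf)
  if (is.matrix(weights)) diag(out) <- 0
  out
}

graph_from_w <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# all-pairs shortest traversal lengths (Inf for unreachable)
length_distances <- function(W) {
  n <- nrow(W)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  g <- graph_from_w(W)
  wts <- if (igraph::ecount(g)) 1 / igraph::E(g)$weight else numeric(0)
  D <- igraph::distances(g, weights = wts, algorithm = "dijkstra")
  D
}

#' Extract a scoped subnetwork
#'
#' @param mat Connectivity matrix with label-name dimnames (assumed in
#'   canonical orientation: the surgical hemisphere on \code{focus_side}).
#' @param parcellation Parcellation supplying side and group tags.
#' @param scope One of "whole_brain", "ipsilateral", "contralateral",
#'   "contralateral_insular".
#' @param focus_side Canonical surgical side (default "right", the
#'   orientation produced by side-flipping).
#' @param retained_labels Optional character vector of label names to
#'   intersect with the scope (e.g. post-resection retained labels).
#' @return Adjacency submatrix on the scoped node set.
#' @export
subnetwork <- function(mat, parcellation,
                       scope = c("whole_brain", "ipsilateral",
                                 "contralateral", "contralateral_insular"),
                       focus_side = "right", retained_labels = NULL) {
  scope <- match.arg(scope)
  labs <- parcellation$labels
  other <- if (focus_side == "right") "left" else "right"
  nodes <- switch(scope,
    whole_brain = labs$name,
    ipsilateral = labs$name[labs$side == focus_side],
    contralateral = labs$name[labs$side == other],
    contralateral_insular = labs$name[labs$side == other &
                                        label_has_group(labs, "insular")])
  nodes <- intersect(nodes, rownames(mat))
  if (!is.null(retained_labels)) nodes <- intersect(nodes, retained_labels)
  mat[nodes, nodes, drop = FALSE]
}

#' Nodal strength
#' @param W Weighted adjacency matrix.
#' @return Named vector of incident-weight sums.
#' @export
nodal_strength <- function(W) rowSums(W)

#' Weighted betweenness centrality
#'
#' Fraction of shortest traversal-length paths between node pairs passing
#' through each node, with equal-length multiplicities split fractionally
#' (Brandes). Normalization divides by (n-1)(n-2)/2, the number of
#' undirected pairs excluding the node.
#'
#' @param W Weighted adjacency matrix.
#' @param normalized Normalize by (n-1)(n-2)/2 (default TRUE).
#' @return Named vector.
#' @export
betweenness_w <- function(W, normalized = TRUE) {
  n <- nrow(W)
  g <- graph_from_w(W)
  wts <- if (igraph::ecount(g)) 1 / igraph::E(g)$weight else numeric(0)
  b <- igraph::betweenness(g, weights = wts, directed = FALSE)
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  stats::setNames(as.numeric(b), rownames(W))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity with weights normalized by the graph
#' maximum: C_i = sum_{j,h} (w'_ij w'_jh w'_hi)^(1/3) / (k_i (k_i - 1)),
#' w' = w / max(w). Nodes of degree < 2 score 0.
#'
#' @param W Weighted adjacency matrix.
#' @return Named vector in [0, 1].
#' @export
clustering_onnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (n == 0) return(stats::setNames(numeric(0), rownames(W)))
  if (mx == 0) return(stats::setNames(numeric(n), rownames(W)))
  A3 <- (W / mx)^(1 / 3)
  tri <- diag(A3 %*% A3 %*% A3)
  k <- rowSums(W > 0)
  C <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(as.numeric(C), rownames(W))
}

#' Global efficiency
#'
#' Mean of inverse shortest traversal lengths over all ordered node pairs
#' (unreachable pairs contribute 0).
#'
#' @param W Weighted adjacency matrix.
#' @return Scalar >= 0.
#' @export
global_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- length_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest traversal length over connected ordered pairs. Disconnected
#' graphs are averaged over reachable pairs only, with a warning (masked
#' clinical networks can fragment).
#'
#' @param W Weighted adjacency matrix.
#' @param warn_disconnected Emit a warning when unreachable pairs exist.
#' @return Scalar (NaN when no pair is connected).
#' @export
char_path_length <- function(W, warn_disconnected = TRUE) {
  n <- nrow(W)
  if (n < 2) return(NaN)
  D <- length_distances(W)
  off <- D[upper.tri(D) | lower.tri(D)]
  if (any(!is.finite(off)) && warn_disconnected)
    warning("graph is disconnected; characteristic path length averaged ",
            "over connected pairs only", call. = FALSE)
  mean(off[is.finite(off)])
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbors, with
#' weights inherited from the full graph. Nodes with fewer than two
#' neighbors score 0.
#'
#' @param W Weighted adjacency matrix.
#' @return Named vector.
#' @export
local_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(W[i, ] > 0)
    if (length(nbrs) < 2) next
    out[i] <- global_efficiency(W[nbrs, nbrs, drop = FALSE])
  }
  stats::setNames(out, rownames(W))
}

#' Small-worldness
#'
#' sigma = (C / <C_null>) / (L / <L_null>), where C is the mean Onnela
#' clustering coefficient, L the characteristic path length, and the null
#' ensemble consists of degree-preserving Maslov-Sneppen edge rewirings of
#' the topology with the original weight multiset randomly reassigned to
#' the rewired edges. Deterministic given \code{seed}.
#'
#' @param W Weighted adjacency matrix (connected, >= 4 nodes).
#' @param n_null Number of null graphs (default 100).
#' @param n_rewires_per_edge Rewiring attempts per edge (default 10).
#' @param seed RNG seed for the null ensemble.
#' @return Scalar sigma.
#' @export
small_worldness <- function(W, n_null = 100L, n_rewires_per_edge = 10L,
                            seed = 1L) {
  n <- nrow(W)
  if (n < 4) stop("small-worldness requires >= 4 nodes", call. = FALSE)
  D <- length_distances(W)
  if (any(!is.finite(D)))
    stop("small-worldness requires a connected graph", call. = FALSE)
  C_obs <- mean(clustering_onnela(W))
  L_obs <- char_path_length(W, warn_disconnected = FALSE)
  g <- graph_from_w(W)
  wts <- igraph::E(g)$weight
  m <- igraph::ecount(g)
  with_seed(seed, {
    Cn <- Ln <- numeric(n_null)
    for (b in seq_len(n_null)) {
      gn <- igraph::rewire(g, igraph::keeping_degseq(
        niter = n_rewires_per_edge * m))
      igraph::E(gn)$weight <- sample(wts)
      Wn <- as.matrix(igraph::as_adjacency_matrix(gn, attr = "weight",
                                                  sparse = FALSE))
      Cn[b] <- mean(clustering_onnela(Wn))
      Ln[b] <- char_path_length(Wn, warn_disconnected = FALSE)
    }
    (C_obs / mean(Cn)) / (L_obs / mean(Ln))
  })
}

#' Regional metric table for one graph
#'
#' @param W Weighted adjacency matrix.
#' @return data.frame: node, betweenness_centrality, clustering_coefficient,
#'   local_efficiency, nodal_strength.
#' @export
node_metrics <- function(W) {
  data.frame(node = rownames(W) %||% as.character(seq_len(nrow(W))),
             betweenness_centrality = as.numeric(betweenness_w(W)),
             clustering_coefficient = as.numeric(clustering_onnela(W)),
             local_efficiency = as.numeric(local_efficiency(W)),
             nodal_strength = as.numeric(nodal_strength(W)),
             stringsAsFactors = FALSE)
}

#' Global metric vector for one graph
#'
#' @param W Weighted adjacency matrix.
#' @param small_world Compute small-worldness (skipped with NA when the
#'   graph is disconnected or has < 4 nodes).
#' @param n_null,n_rewires_per_edge,seed Passed to [small_worldness()].
#' @return Named numeric of the six global measures.
#' @export
global_metrics <- function(W, small_world = TRUE, n_null = 100L,
                           n_rewires_per_edge = 10L, seed = 1L) {
  sw <- NA_real_
  if (small_world) {
    sw <- tryCatch(
      small_worldness(W, n_null = n_null,
                      n_rewires_per_edge = n_rewires_per_edge, seed = seed),
      error = function(e) NA_real_)
  }
  c(characteristic_path_length = char_path_length(W,
                                                  warn_disconnected = FALSE),
    global_efficiency = global_efficiency(W),
    small_worldness = sw,
    average_betweenness_centrality = mean(betweenness_w(W)),
    average_clustering_coefficient = mean(clustering_onnela(W)),
    average_nodal_strength = mean(nodal_strength(W)))
}
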