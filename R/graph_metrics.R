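as_adj_matrix <- function(x) {
  a <- if (inherits(x, "functional_network")) x$adjacency else as.matrix(x)
  stop_if_not(isTRUE(all.equal(a, t(a))), "adjacency must be symmetric")
  stop_if_not(all(a %in% c(0, 1)), "adjacency must be binary")
  diag(a) <- 0
  a
}

adj_list <- function(a) {
  apply(a, 1, function(r) which(r == 1), simplify = FALSE)
}

#' Nodal degree
#'
#' Number of edges incident to each node — the hubness measure.
#'
#' @param adjacency binary symmetric matrix or `functional_network`.
#' @return Integer vector of length V.
#' @export
nodal_degree <- function(adjacency) {
  as.integer(rowSums(as_adj_matrix(adjacency)))
}

#' Nodal clustering coefficient
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node i; defined as 0 for nodes of degree < 2. A segregation
#' measure.
#'
#' @inheritParams nodal_degree
#' @return Numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  k <- rowSums(a)
  tri <- rowSums((a %*% a) * a) / 2
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  as.numeric(cc)
}

#' Nodal betweenness centrality
#'
#' Unnormalised shortest-path betweenness (Brandes accumulation over
#' unweighted geodesics); node pairs in different components contribute
#' nothing. A within-network communication measure. The downstream
#' disruption-index regression is scale-equivariant, so the unnormalised
#' convention only rescales slopes.
#'
#' @inheritParams nodal_degree
#' @return Numeric vector, each entry in `[0, (V-1)(V-2)/2]`.
#' @export
betweenness_centrality <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  .cpp_betweenness(adj_list(a))
}

#' Nodal efficiency
#'
#' `E_i = mean_j 1/d_ij` over all other nodes j, with `1/d_ij := 0` for
#' unreachable pairs; distances from unweighted breadth-first search. An
#' integration measure, 1 on the complete graph.
#'
#' @inheritParams nodal_degree
#' @return Numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  v <- nrow(a)
  d <- .cpp_bfs_distances(adj_list(a))
  inv <- ifelse(d > 0, 1 / d, 0)
  rowSums(inv) / (v - 1)
}

#' Module partition by greedy modularity maximisation
#'
#' Deterministic (seeded) greedy agglomerative modularity optimisation;
#' isolated nodes become singleton modules. This supplies the community
#' structure required by the participation coefficient, which needs a
#' partition the connectivity data alone do not dictate. Alternatively a
#' fixed partition (e.g. from the control-group mean network) can be passed
#' straight to [participation_coefficient()].
#'
#' @inheritParams nodal_degree
#' @param seed integer seed (the greedy pass is deterministic; the seed
#'   fixes any internal tie-breaking).
#' @return List of class `hd_partition`: `module_id` (integer labels,
#'   contiguous from 1) and `modularity`.
#' @export
detect_modules <- function(adjacency, seed = 1) {
  a <- as_adj_matrix(adjacency)
  stop_if_not(sum(a) > 0, "graph has no edges")
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cl <- igraph::cluster_fast_greedy(g)
  labs <- as.integer(igraph::membership(cl))
  labs <- match(labs, unique(labs)) # contiguous from 1
  q <- igraph::modularity(g, labs)
  if (q <= 0) { # no split beats the trivial partition (e.g. complete graph)
    labs <- rep(1L, nrow(a))
    q <- igraph::modularity(g, labs)
  }
  structure(list(module_id = labs, modularity = q),
            class = "hd_partition")
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2` over modules m, where `k_im` is the
#' number of links from i into module m; 0 for isolated nodes. A diversity
#' measure: 0 when all links stay in one module, approaching 1 when links
#' spread evenly over many modules.
#'
#' @inheritParams nodal_degree
#' @param partition an `hd_partition` or integer module-label vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(adjacency, partition) {
  a <- as_adj_matrix(adjacency)
  labs <- if (inherits(partition, "hd_partition")) partition$module_id
          else as.integer(partition)
  stop_if_not(length(labs) == nrow(a), "partition must cover all nodes")
  k <- rowSums(a)
  mods <- sort(unique(labs))
  kim2 <- matrix(0, nrow(a), length(mods))
  for (j in seq_along(mods))
    kim2[, j] <- rowSums(a[, labs == mods[j], drop = FALSE])^2
  p <- ifelse(k > 0, 1 - rowSums(kim2) / k^2, 0)
  as.numeric(p)
}

#' All five nodal metrics of a binary network
#'
#' Degree, clustering coefficient, betweenness centrality, nodal efficiency
#' and participation coefficient in one call (sharing the module partition).
#'
#' @inheritParams nodal_degree
#' @param partition optional partition for the participation coefficient;
#'   computed by [detect_modules()] when omitted.
#' @param seed seed for [detect_modules()].
#' @return Data frame with columns `node`, `D`, `BC`, `CC`, `E`, `PC`.
#' @export
nodal_metrics <- function(adjacency, partition = NULL, seed = 1) {
  a <- as_adj_matrix(adjacency)
  if (is.null(partition)) partition <- detect_modules(a, seed = seed)
  data.frame(node = seq_len(nrow(a)),
             D = nodal_degree(a),
             BC = betweenness_centrality(a),
             CC = clustering_coefficient(a),
             E = nodal_efficiency(a),
             PC = participation_coefficient(a, partition))
}
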