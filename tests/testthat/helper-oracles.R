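# Independent oracles and small fixtures, all built in code.

# Erdos-Renyi adjacency with exactly fixed edge probability (for oracle
# comparisons; edge count varies).
random_adjacency <- function(v, p, seed) {
  set.seed(seed)
  a <- matrix(0L, v, v)
  a[upper.tri(a)] <- as.integer(runif(v * (v - 1) / 2) < p)
  a + t(a)
}

# Floyd-Warshall distances and geodesic counts -> brute-force betweenness
# (independent of the BFS/Brandes path in the package).
brute_betweenness <- function(a) {
  v <- nrow(a)
  d <- matrix(Inf, v, v)
  cnt <- matrix(0, v, v)
  d[a == 1] <- 1
  cnt[a == 1] <- 1
  diag(d) <- 0
  diag(cnt) <- 1
  for (k in seq_len(v)) for (i in seq_len(v)) for (j in seq_len(v)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) { d[i, j] <- alt; cnt[i, j] <- cnt[i, k] * cnt[k, j] }
    else if (alt == d[i, j] && is.finite(alt))
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
  }
  bc <- numeric(v)
  for (w in seq_len(v)) {
    tot <- 0
    for (i in seq_len(v)) for (j in seq_len(v)) {
      if (i >= j || i == w || j == w) next
      if (!is.finite(d[i, j]) || d[i, j] < 2) next
      if (d[i, w] + d[w, j] == d[i, j])
        tot <- tot + cnt[i, w] * cnt[w, j] / cnt[i, j]
    }
    bc[w] <- tot
  }
  bc
}

brute_efficiency <- function(a) {
  v <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (v - 1)
}

brute_participation <- function(a, labs) {
  v <- nrow(a)
  k <- rowSums(a)
  sapply(seq_len(v), function(i) {
    if (k[i] == 0) return(0)
    1 - sum(sapply(unique(labs), function(m)
      (sum(a[i, labs == m]) / k[i])^2))
  })
}

# Exhaustive per-threshold connected-component TFCE oracle (plain R, BFS).
brute_tfce <- function(stat, neighbors, E = 0.5, H = 2, dh) {
  v <- length(stat)
  out <- numeric(v)
  mx <- max(stat)
  if (mx <= 0) return(out)
  hs <- seq_len(floor(mx / dh + 1e-9)) * dh
  for (h in hs) {
    active <- stat >= h
    seen <- rep(FALSE, v)
    for (s in which(active)) {
      if (seen[s]) next
      comp <- s
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (w in neighbors[[u]]) if (active[w] && !seen[w]) {
          seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
        }
      }
      out[comp] <- out[comp] + length(comp)^E * h^H * dh
    }
  }
  out
}

# Small deterministic grid helper for map tests.
toy_grid <- function(nx, ny = 1, nz = 1) {
  as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz)))
}
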