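# Shared fixtures and independent oracles for the test suite.

upper_edges <- structnet:::upper_edges  # internal helper used by fixtures

flat_atlas <- function(n) {
  region_atlas(data.frame(
    id = seq_len(n), label = sprintf("N%02d", seq_len(n)),
    hemisphere = rep_len(c("left", "right"), n),
    x = 0, y = 0, z = 0, volume = 100L))
}

# connectome from an upper-triangle edge list (i, j, w)
edge_connectome <- function(n, edges, id = "fix") {
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    W[edges[e, 1], edges[e, 2]] <- edges[e, 3]
    W[edges[e, 2], edges[e, 1]] <- edges[e, 3]
  }
  connectome(W, flat_atlas(n), id)
}

# random symmetric nonnegative weight matrix (Bernoulli edges, Unif weights)
random_weight_matrix <- function(n, p = 0.5, wmax = 2) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(ut)) < p
  w <- ifelse(on, runif(nrow(ut), 0.05, wmax), 0)
  W[ut] <- w
  W[ut[, 2:1]] <- w
  W
}

random_connectome <- function(n, p = 0.5, wmax = 2, id = "rnd") {
  connectome(random_weight_matrix(n, p, wmax), flat_atlas(n), id)
}

# ---- independent oracles -------------------------------------------------

# All-pairs shortest paths on lengths 1/w by Floyd-Warshall.
fw_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_nodal_efficiency <- function(W) {
  D <- fw_distances(W)
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    inv <- 1 / D[i, -i]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  })
}

# Brute-force weighted rich-club coefficient (explicit loops).
oracle_weighted_phi <- function(W, k) {
  deg <- colSums(W > 0)
  S <- which(deg > k)
  if (length(S) < 2) return(NA_real_)
  within <- c()
  for (a in seq_along(S)) for (b in seq_along(S))
    if (a < b && W[S[a], S[b]] > 0) within <- c(within, W[S[a], S[b]])
  if (length(within) == 0) return(NA_real_)
  all_w <- c()
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (i < j && W[i, j] > 0) all_w <- c(all_w, W[i, j])
  sum(within) / sum(sort(all_w, decreasing = TRUE)[seq_along(within)])
}

# Connected components of an edge list by BFS; returns per-component
# edge counts (sorted decreasing) -- independent of igraph.
oracle_component_extents <- function(ei, ej, n) {
  if (length(ei) == 0) return(integer(0))
  adj <- vector("list", n)
  for (e in seq_along(ei)) {
    adj[[ei[e]]] <- c(adj[[ei[e]]], ej[e])
    adj[[ej[e]]] <- c(adj[[ej[e]]], ei[e])
  }
  comp <- integer(n)
  cc <- 0L
  for (s in unique(c(ei, ej))) {
    if (comp[s] == 0L) {
      cc <- cc + 1L
      queue <- s
      comp[s] <- cc
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        for (u in adj[[v]]) if (comp[u] == 0L) {
          comp[u] <- cc
          queue <- c(queue, u)
        }
      }
    }
  }
  extents <- sapply(seq_len(cc), function(c) {
    sum(comp[ei] == c)
  })
  sort(extents, decreasing = TRUE)
}

# Exhaustive maximum-modularity search over all set partitions.
oracle_max_modularity <- function(W) {
  parts <- structnet:::all_set_partitions(nrow(W))
  max(vapply(parts, function(m) modularity_q(W, m), numeric(1)))
}
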