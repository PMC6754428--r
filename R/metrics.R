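#' Weighted shortest-path length matrix
#'
#' Dijkstra distances over edge lengths `1/w` for `w > 0` (the standard
#' weight-to-length map in weighted connectomics: stronger connections
#' are shorter). Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @param C a [connectome()] or a plain symmetric weight matrix.
#' @return N x N numeric matrix of distances.
#' @export
shortest_path_lengths <- function(C) {
  W <- if (inherits(C, "connectome")) C$weights else C
  g <- as_weighted_graph(W)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  D
}

#' Nodal efficiency
#'
#' `e_nodal(i)` is the mean over all other nodes j of `1/d(i, j)`
#' (with `1/Inf = 0`): how efficiently node i reaches the rest of the
#' network. Highly connected integrative nodes ("hubs") score high.
#'
#' @param C a [connectome()] or weight matrix.
#' @return Numeric vector of per-node efficiencies.
#' @export
nodal_efficiency <- function(C) {
  D <- shortest_path_lengths(C)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(D) - 1)
}

#' Global and local efficiency
#'
#' Global efficiency is the mean of `1/d` over all ordered node pairs.
#' Local efficiency of node i is the global efficiency of the subgraph
#' induced by i's neighbours (0 when i has fewer than two neighbours).
#'
#' @param C a [connectome()] or weight matrix.
#' @return List with `global` (scalar) and `local` (per-node vector).
#' @export
global_and_local_efficiency <- function(C) {
  W <- if (inherits(C, "connectome")) C$weights else C
  glob <- mean_inverse_distance(W)
  n <- nrow(W)
  loc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) >= 2)
      loc[i] <- mean_inverse_distance(W[nb, nb, drop = FALSE])
  }
  list(global = glob, local = loc)
}

# Mean of 1/d over ordered off-diagonal pairs (0 when n < 2).
mean_inverse_distance <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- shortest_path_lengths(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node weighted clustering on weights rescaled by the matrix
#' maximum: `C_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))`
#' with binary degree `k_i`; nodes with `k_i < 2` get 0.
#'
#' @param C a [connectome()] or weight matrix.
#' @return Numeric vector of per-node clustering coefficients.
#' @export
weighted_clustering <- function(C) {
  W <- if (inherits(C, "connectome")) C$weights else C
  mx <- max(W)
  if (mx <= 0) return(numeric(nrow(W)))
  W3 <- (W / mx)^(1 / 3)
  cyc <- diag(W3 %*% W3 %*% W3)
  k <- binary_degree(W)
  out <- numeric(nrow(W))
  ok <- k >= 2
  out[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs. Disconnected graphs are
#' handled by averaging over the finite pairs only; the result then
#' carries the attribute `disconnected = TRUE`.
#'
#' @param C a [connectome()] or weight matrix.
#' @return Scalar path length (possibly with a `disconnected`
#'   attribute).
#' @export
char_path_length <- function(C) {
  D <- shortest_path_lengths(C)
  off <- D[upper.tri(D)]
  fin <- off[is.finite(off)]
  disconnected <- length(fin) < length(off)
  if (disconnected)
    warning("graph is disconnected; path length averaged over finite pairs")
  out <- if (length(fin)) mean(fin) else Inf
  attr(out, "disconnected") <- disconnected
  out
}

#' Clustering, path length and small-world index
#'
#' The small-world index is
#' `sigma = (C / C_rand) / (L / L_rand)`, where `C` is the mean
#' weighted clustering coefficient, `L` the characteristic path
#' length, and the `_rand` references are means over `n_random`
#' degree-preserving randomisations of the network (topology rewired
#' by double-edge swaps, weights permuted). `sigma > 1` indicates
#' small-world organisation.
#'
#' @param C a [connectome()] or weight matrix.
#' @param n_random number of null networks (default 100).
#' @param seed seed for the randomisations.
#' @return List with `mean_clustering`, `char_path_length`,
#'   `small_world_sigma` and the null means.
#' @export
clustering_path_smallworld <- function(C, n_random = 100, seed = NULL) {
  W <- if (inherits(C, "connectome")) C$weights else C
  cw <- mean(weighted_clustering(W))
  lw <- suppressWarnings(char_path_length(W))
  cr <- numeric(n_random)
  lr <- numeric(n_random)
  with_seed(seed, {
    for (r in seq_len(n_random)) {
      Wr <- rewire_preserve_degree(W)
      cr[r] <- mean(weighted_clustering(Wr))
      lr[r] <- suppressWarnings(as.numeric(char_path_length(Wr)))
    }
  })
  sigma <- (cw / mean(cr)) / (as.numeric(lw) / mean(lr))
  list(mean_clustering = cw, char_path_length = as.numeric(lw),
       disconnected = isTRUE(attr(lw, "disconnected")),
       small_world_sigma = sigma,
       clustering_random = mean(cr), path_length_random = mean(lr))
}

#' Participation coefficient
#'
#' `PC(i) = 1 - sum_c (k_ic / k_i)^2`, where `k_i` is node i's binary
#' degree and `k_ic` its number of links into module c. 0 means all
#' links stay inside one module; values near 1 mean links spread evenly
#' across modules. Isolated nodes get 0 by convention.
#'
#' @param C a [connectome()] or weight matrix.
#' @param membership integer module id per node (or a `partition`
#'   object from [louvain_best()]).
#' @return Numeric vector of per-node participation coefficients.
#' @export
participation_coefficient <- function(C, membership) {
  W <- if (inherits(C, "connectome")) C$weights else C
  m <- membership_vector(membership, nrow(W))
  A <- W > 0
  k <- colSums(A)
  mods <- sort(unique(m))
  # k_ic: links of node i into module c
  kic <- vapply(mods, function(c) colSums(A[m == c, , drop = FALSE]),
                numeric(nrow(W)))
  pc <- numeric(nrow(W))
  pos <- k > 0
  pc[pos] <- 1 - rowSums((kic[pos, , drop = FALSE] / k[pos])^2)
  pc
}

#' Within-module degree z-score
#'
#' For node i in module c, `z(i)` standardises i's number of
#' within-module links against the distribution of within-module
#' degrees of all nodes in c (sample SD). Modules with zero variance or
#' a single member give z = 0.
#'
#' @inheritParams participation_coefficient
#' @return Numeric vector of per-node z-scores.
#' @export
within_module_z <- function(C, membership) {
  W <- if (inherits(C, "connectome")) C$weights else C
  m <- membership_vector(membership, nrow(W))
  A <- W > 0
  z <- numeric(nrow(W))
  for (c in unique(m)) {
    nodes <- which(m == c)
    kw <- colSums(A[nodes, nodes, drop = FALSE])
    if (length(nodes) >= 2) {
      s <- stats::sd(kw)
      if (s > 0) z[nodes] <- (kw - mean(kw)) / s
    }
  }
  z
}

# Accept a partition object or raw membership vector.
membership_vector <- function(membership, n) {
  m <- if (inherits(membership, "partition")) membership$assignment
       else as.integer(membership)
  if (length(m) != n) stopf("partition does not cover all %d nodes", n)
  m
}

#' Per-node metric table
#'
#' Assembles degree, strength, nodal efficiency (raw and normalised by
#' the network mean), weighted clustering, participation coefficient
#' and within-module degree z-score into one data frame.
#'
#' @param C a [connectome()].
#' @param partition a partition (from [louvain_best()]) or membership
#'   vector; PC and z columns are `NA` when omitted.
#' @return Data frame with one row per region.
#' @export
node_metrics <- function(C, partition = NULL) {
  W <- C$weights
  e <- nodal_efficiency(W)
  df <- data.frame(
    node = seq_len(nrow(W)),
    label = C$atlas$label,
    degree = binary_degree(W),
    strength = colSums(W),
    e_nodal = e,
    e_nodal_norm = if (mean(e) > 0) e / mean(e) else NA_real_,
    clustering = weighted_clustering(W)
  )
  if (!is.null(partition)) {
    df$pc <- participation_coefficient(W, partition)
    df$z_within <- within_module_z(W, partition)
  } else {
    df$pc <- NA_real_
    df$z_within <- NA_real_
  }
  df
}

#' Global metric summary
#'
#' Connection density, global efficiency, characteristic path length,
#' mean weighted clustering, small-world index and (optionally)
#' modularity of a supplied or freshly optimised partition.
#'
#' @param C a [connectome()].
#' @param partition optional partition for the modularity entry; when
#'   `NULL` one is found with [louvain_best()] (`n_restarts` restarts).
#' @param n_random null networks for the small-world index.
#' @param n_restarts Louvain restarts when `partition` is `NULL`.
#' @param seed RNG seed.
#' @return One-row data frame.
#' @export
global_metrics <- function(C, partition = NULL, n_random = 100,
                           n_restarts = 100, seed = NULL) {
  W <- C$weights
  n <- nrow(W)
  ed <- upper_edges(W)
  sw <- clustering_path_smallworld(W, n_random = n_random,
                                   seed = derive_seed(seed %||% 0L, 1))
  if (is.null(partition))
    partition <- louvain_best(C, n_restarts = n_restarts,
                              seed = derive_seed(seed %||% 0L, 2))
  data.frame(
    density = nrow(ed) / (n * (n - 1) / 2),
    global_efficiency = global_and_local_efficiency(W)$global,
    char_path_length = sw$char_path_length,
    mean_clustering = sw$mean_clustering,
    small_world_sigma = sw$small_world_sigma,
    modularity_q = partition$q,
    n_modules = partition$n_modules
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
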