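# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a master seed and an offset.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 48271 + as.double(offset) * 104729) %%
               2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_square_numeric <- function(W, what = "matrix") {
  if (!is.matrix(W) || !is.numeric(W))
    stopf("%s must be a numeric matrix", what)
  if (nrow(W) != ncol(W))
    stopf("%s must be square (got %d x %d)", what, nrow(W), ncol(W))
  bad <- which(is.na(W), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("%s has a missing/NaN entry at [%d, %d]", what, bad[1, 1], bad[1, 2])
  bad <- which(W < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("%s has a negative entry at [%d, %d]", what, bad[1, 1], bad[1, 2])
  invisible(W)
}

# Upper-triangle edge list of a weighted adjacency matrix: i < j, w > 0.
upper_edges <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
}

# igraph view of a weighted adjacency matrix (undirected, no self loops).
as_weighted_graph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Binary degree: number of nonzero neighbours per node.
binary_degree <- function(W) as.integer(colSums(W > 0))

# Union-find over nodes 1..n; returns the largest edge count carried by a
# single connected component of the given edge list. Used on the hot path of
# the NBS permutation loop where building a full graph object per permutation
# would dominate runtime.
max_component_extent <- function(ei, ej, n) {
  m <- length(ei)
  if (m == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(m)) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, integer(1))
  max(tabulate(roots, nbins = n))
}

# Enumerate all set partitions of n elements as restricted growth strings.
# Exponential (Bell number) -- intended for oracle checks on tiny n only.
all_set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(pos, maxv) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- rgs + 1L
      return(invisible(NULL))
    }
    for (v in 0:(maxv + 1L)) {
      rgs[pos] <<- v
      recurse(pos + 1L, max(maxv, v))
    }
  }
  recurse(2L, 0L)  # first element always in block 0
  out
}

# Canonicalise a module assignment to first-appearance order, ids 1..K.
canonical_membership <- function(membership) {
  ids <- unique(membership)
  match(membership, ids)
}
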