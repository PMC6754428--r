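# Degree-preserving randomisation of a weighted matrix: Maslov-Sneppen
# double-edge swaps on the topology, then a random permutation of the
# weight multiset over the rewired edges. Preserves the binary degree
# sequence exactly and the weight multiset exactly.
rewire_preserve_degree <- function(W, n_swaps_per_edge = 10) {
  g <- as_weighted_graph(W)
  m <- igraph::ecount(g)
  if (m < 2) {
    warning("fewer than 2 edges; returning input unchanged")
    return(W)
  }
  w <- igraph::E(g)$weight
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps_per_edge * m))
  el <- igraph::as_edgelist(gr, names = FALSE)
  Ar <- matrix(0, nrow(W), ncol(W))
  Ar[el] <- 1
  Ar[el[, 2:1, drop = FALSE]] <- 1
  if (all(Ar == (W > 0)))
    warning("topology unchanged by rewiring (graph may admit no swap)")
  out <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  wperm <- sample(w)
  out[el] <- wperm
  out[el[, 2:1, drop = FALSE]] <- wperm
  out
}

#' Degree-preserving randomisation of a connectome
#'
#' Rewires the topology by Maslov-Sneppen double-edge swaps (binary
#' degree sequence exactly preserved) and re-assigns the original
#' weight multiset to the rewired edges by random permutation — the
#' standard null model for weighted rich-club normalisation. Graphs
#' admitting no swap (e.g. a star) are returned unchanged with a
#' warning.
#'
#' @param C a [connectome()].
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return A randomised [connectome()].
#' @export
degree_preserving_randomize <- function(C, n_swaps_per_edge = 10,
                                        seed = NULL) {
  with_seed(seed, {
    connectome(rewire_preserve_degree(C$weights, n_swaps_per_edge),
               C$atlas, paste0(C$subject_id, "-rand"))
  })
}

#' Weighted rich-club coefficient at one degree level
#'
#' For the subnetwork S of nodes with binary degree `> k`,
#' `phi(k)` is the sum of edge weights inside S divided by the sum of
#' the `E_S` largest edge weights anywhere in the network, where `E_S`
#' is the number of edges inside S. Undefined (NA, with attribute
#' `reason`) when S is empty or contains no edge.
#'
#' @param C a [connectome()] or weight matrix.
#' @param k degree level.
#' @return `phi(k)` in (0, 1], or `NA` when undefined.
#' @export
weighted_phi <- function(C, k) {
  W <- if (inherits(C, "connectome")) C$weights else C
  deg <- binary_degree(W)
  S <- which(deg > k)
  if (length(S) < 2) return(structure(NA_real_, reason = "empty club"))
  sub <- W[S, S, drop = FALSE]
  ed_sub <- upper_edges(sub)
  e_s <- nrow(ed_sub)
  if (e_s == 0) return(structure(NA_real_, reason = "edgeless club"))
  all_w <- sort(upper_edges(W)$w, decreasing = TRUE)
  sum(ed_sub$w) / sum(all_w[seq_len(e_s)])
}

#' Normalised weighted rich-club curve
#'
#' Computes `phi(k)` for `k = 1 .. max_degree - 1`, the null mean
#' `phi_random(k)` over `n_random` degree-preserving randomisations
#' ([degree_preserving_randomize()]), and their ratio
#' `phi_norm(k) = phi(k) / phi_random(k)`. `phi_norm > 1` over a range
#' of k indicates rich-club organisation: the high-degree core is more
#' strongly interconnected than degree-matched chance. Levels where
#' the club is empty or edgeless are reported as `NA`.
#'
#' @param C a [connectome()].
#' @param n_random number of null networks (default 1000).
#' @param n_swaps_per_edge swaps per edge for each null.
#' @param seed RNG seed.
#' @return A `rich_club_curve`: data frame with columns `k`, `phi`,
#'   `phi_random_mean`, `phi_norm`, plus attributes `members_at_k`
#'   (list of node-index vectors) and `n_random`.
#' @export
normalized_rich_club <- function(C, n_random = 1000, n_swaps_per_edge = 10,
                                 seed = NULL) {
  W <- C$weights
  deg <- binary_degree(W)
  kmax <- max(deg)
  if (kmax < 2) stopf("degenerate network: maximum degree < 2")
  ks <- seq_len(kmax - 1L)
  phi <- vapply(ks, function(k) as.numeric(weighted_phi(W, k)), numeric(1))
  phi_rand <- matrix(NA_real_, n_random, length(ks))
  with_seed(seed, {
    for (r in seq_len(n_random)) {
      Wr <- suppressWarnings(rewire_preserve_degree(W, n_swaps_per_edge))
      phi_rand[r, ] <- vapply(ks, function(k) as.numeric(weighted_phi(Wr, k)),
                              numeric(1))
    }
  })
  phi_rand_mean <- colMeans(phi_rand, na.rm = TRUE)
  phi_rand_mean[is.nan(phi_rand_mean)] <- NA_real_
  out <- data.frame(k = ks, phi = phi, phi_random_mean = phi_rand_mean,
                    phi_norm = phi / phi_rand_mean)
  attr(out, "members_at_k") <- lapply(ks, function(k) which(deg > k))
  attr(out, "n_random") <- n_random
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Rich-club members at a degree level
#'
#' @param curve a [normalized_rich_club()] result.
#' @param k degree level present in the curve.
#' @return Integer vector of member node indices (degree > k).
#' @export
rich_club_members <- function(curve, k) {
  i <- match(k, curve$k)
  if (is.na(i)) stopf("k = %d outside the curve range", k)
  attr(curve, "members_at_k")[[i]]
}

#' Rich-connector-hub network
#'
#' The backbone of inter-modular integration carried by the rich club:
#' nodes that are simultaneously rich-club members at level `k_star`
#' and connector hubs, together with their existing connections to any
#' connector hub in the network.
#'
#' @param C a [connectome()].
#' @param curve a [normalized_rich_club()] result.
#' @param k_star degree level at which membership is taken (typically
#'   the `phi_norm` peak).
#' @param hubs a hub table from [classify_hubs()].
#' @return Data frame of edges (`i`, `j`, `w`); zero rows when the
#'   rich-club/connector intersection is empty.
#' @export
rich_connector_hub_network <- function(C, curve, k_star, hubs) {
  members <- rich_club_members(curve, k_star)
  connectors <- hubs$node[hubs$hub_class == "connector"]
  core <- intersect(members, connectors)
  W <- C$weights
  out <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  for (i in core) {
    for (j in connectors) {
      if (i != j && W[i, j] > 0) {
        a <- min(i, j); b <- max(i, j)
        out <- rbind(out, data.frame(i = a, j = b, w = W[a, b]))
      }
    }
  }
  unique(out)
}
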