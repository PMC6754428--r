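#' Partition object
#'
#' A node-to-module assignment with its weighted modularity score.
#' Module ids are canonicalised to first-appearance order (1..K).
#'
#' @param assignment integer module id per node.
#' @param C optional [connectome()] or weight matrix used to compute
#'   the modularity score.
#' @return A `partition` (list with `assignment`, `q`, `n_modules`).
#' @export
partition <- function(assignment, C = NULL) {
  m <- canonical_membership(as.integer(assignment))
  q <- if (is.null(C)) NA_real_ else modularity_q(C, m)
  structure(list(assignment = m, q = q, n_modules = length(unique(m))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d modules, Q = %.4f\n", x$n_modules, x$q))
  invisible(x)
}

#' Weighted Newman modularity
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * [c_i == c_j]`, with
#' `s_i` node strength and `2m` the total weight. Positive Q means
#' more within-module weight than expected under the configuration
#' model.
#'
#' @param C a [connectome()] or weight matrix.
#' @param membership module ids per node (or a [partition()]).
#' @return Scalar modularity.
#' @export
modularity_q <- function(C, membership) {
  W <- if (inherits(C, "connectome")) C$weights else C
  m <- membership_vector(membership, nrow(W))
  two_m <- sum(W)
  if (two_m <= 0) return(0)
  s <- colSums(W)
  q <- 0
  for (c in unique(m)) {
    idx <- m == c
    q <- q + sum(W[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2
  }
  q
}

#' Louvain community detection with restarts
#'
#' Runs the Louvain algorithm `n_restarts` times under distinct
#' sub-seeds (each restart permutes the node order, the main source of
#' variability in the greedy optimisation) and keeps the partition with
#' the largest weighted modularity. Ties are broken by the
#' lexicographically smallest canonical assignment so results are
#' reproducible.
#'
#' @param C a [connectome()] or weight matrix.
#' @param n_restarts number of restarts (default 1000).
#' @param seed master seed; restart r uses the derived seed
#'   `derive(seed, r)`.
#' @return A [partition()].
#' @export
louvain_best <- function(C, n_restarts = 1000, seed = NULL) {
  W <- if (inherits(C, "connectome")) C$weights else C
  if (max(W) <= 0) stopf("cannot partition an all-zero network")
  n <- nrow(W)
  best_m <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    m <- with_seed(derive_seed(seed %||% 0L, r), {
      perm <- sample.int(n)
      gp <- as_weighted_graph(W[perm, perm])
      mm <- igraph::membership(igraph::cluster_louvain(gp))
      out <- integer(n)
      out[perm] <- as.integer(mm)
      out
    })
    m <- canonical_membership(m)
    q <- modularity_q(W, m)
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && !is.null(best_m) &&
         lexicographically_less(m, best_m))) {
      best_q <- q
      best_m <- m
    }
  }
  structure(list(assignment = best_m, q = best_q,
                 n_modules = length(unique(best_m))),
            class = "partition")
}

lexicographically_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Hub identification by normalised nodal efficiency
#'
#' Nodal efficiencies are normalised by their mean (so the normalised
#' mean is 1); a node is a hub when its normalised efficiency exceeds
#' 1 plus one (sample) SD of the normalised values. The rule is
#' invariant to global rescaling of the efficiencies.
#'
#' @param e_nodal numeric vector of nodal efficiencies.
#' @return Logical hub flag per node, with attribute `e_nodal_norm`.
#' @export
hubs_by_efficiency <- function(e_nodal) {
  if (length(e_nodal) < 2) stopf("need at least 2 nodes")
  mu <- mean(e_nodal)
  if (mu <= 0) stopf("mean nodal efficiency is zero; hubs undefined")
  norm <- e_nodal / mu
  flags <- norm > 1 + stats::sd(norm)
  attr(flags, "e_nodal_norm") <- norm
  flags
}

#' Hub table with provincial/connector taxonomy
#'
#' Combines the efficiency-based hub flag with the modular taxonomy:
#' nodes whose within-module degree z-score exceeds the mean-plus-SD of
#' all nodes are classed `provincial` when their participation
#' coefficient is at most 0.3 (intra-modular communication) and
#' `connector` when it exceeds 0.3 (inter-modular communication);
#' everything else is `none`.
#'
#' @param C a [connectome()].
#' @param partition a [partition()] or membership vector.
#' @return Data frame with columns `node`, `label`, `e_nodal`,
#'   `e_nodal_norm`, `is_hub`, `z_within`, `pc`, `hub_class`.
#' @export
classify_hubs <- function(C, partition) {
  W <- C$weights
  e <- nodal_efficiency(W)
  flags <- hubs_by_efficiency(e)
  z <- within_module_z(W, partition)
  pc <- participation_coefficient(W, partition)
  z_thr <- mean(z) + stats::sd(z)
  high_z <- z > z_thr
  hub_class <- ifelse(!high_z, "none",
                      ifelse(pc <= 0.3, "provincial", "connector"))
  data.frame(node = seq_len(nrow(W)), label = C$atlas$label,
             e_nodal = e, e_nodal_norm = attr(flags, "e_nodal_norm"),
             is_hub = as.logical(flags), z_within = z, pc = pc,
             hub_class = hub_class, stringsAsFactors = FALSE)
}

# NMI between two memberships; identical partitions count as 1 even in
# the degenerate single-module case where the entropy normalisation is
# 0/0.
nmi_partitions <- function(a, b) {
  ca <- canonical_membership(a)
  cb <- canonical_membership(b)
  if (identical(ca, cb)) return(1)
  igraph::compare(ca, cb, method = "nmi")
}

#' Select the reference community structure for group comparison
#'
#' For each group, the group-average matrix is partitioned with
#' [louvain_best()] and a goodness-of-fit score is computed as the mean
#' normalised mutual information (NMI) between that group partition and
#' each subject's individual partition. The group partition with the
#' higher mean goodness is returned as the shared reference scheme for
#' modular fingerprinting; ties fall back to group A with a warning.
#'
#' @param groupA,groupB [cohort()] objects.
#' @param n_restarts Louvain restarts for the group-average partitions.
#' @param n_restarts_subject Louvain restarts per subject partition.
#' @param seed RNG seed.
#' @param method partition-similarity score: `"nmi"` (default) or
#'   `"adjusted.rand"`.
#' @return List with `reference` ([partition()]), `selected` (group
#'   label), and `goodness` (named mean similarity scores).
#' @export
select_reference_partition <- function(groupA, groupB, n_restarts = 1000,
                                       n_restarts_subject = 100,
                                       seed = NULL,
                                       method = c("nmi", "adjusted.rand")) {
  method <- match.arg(method)
  score_group <- function(ch, offset) {
    gp <- louvain_best(group_average(ch), n_restarts = n_restarts,
                       seed = derive_seed(seed %||% 0L, offset))
    nmis <- vapply(seq_along(ch$subjects), function(s) {
      sp <- louvain_best(ch$subjects[[s]], n_restarts = n_restarts_subject,
                         seed = derive_seed(seed %||% 0L, offset + s))
      if (method == "nmi") nmi_partitions(gp$assignment, sp$assignment)
      else igraph::compare(gp$assignment, sp$assignment,
                           method = "adjusted.rand")
    }, numeric(1))
    list(partition = gp, goodness = mean(nmis))
  }
  a <- score_group(groupA, 1000L)
  b <- score_group(groupB, 2000L)
  goodness <- c(a$goodness, b$goodness)
  names(goodness) <- c(groupA$group_label, groupB$group_label)
  if (a$goodness == b$goodness)
    warning("goodness-of-fit tie; selecting group A's partition")
  sel <- if (b$goodness > a$goodness) "B" else "A"
  list(reference = if (sel == "A") a$partition else b$partition,
       selected = names(goodness)[if (sel == "A") 1 else 2],
       goodness = goodness)
}

#' Modular connectivity fingerprint
#'
#' Edge-count maps over a reference partition: `intra[c]` counts edges
#' with both endpoints in module c, `inter[a, b]` counts edges linking
#' modules a and b, and `connector_inter` restricts the inter-module
#' counts to edges incident to at least one connector hub.
#'
#' @param C a [connectome()].
#' @param reference a [partition()] (the shared reference scheme).
#' @param hubs optional hub table from [classify_hubs()]; when omitted
#'   the connector map is all zero.
#' @return List with `intra` (vector), `inter` (symmetric matrix) and
#'   `connector_inter` (symmetric matrix).
#' @export
modular_fingerprint <- function(C, reference, hubs = NULL) {
  W <- C$weights
  m <- membership_vector(reference, nrow(W))
  K <- max(m)
  ed <- upper_edges(W)
  ma <- m[ed$i]
  mb <- m[ed$j]
  intra <- vapply(seq_len(K), function(c) sum(ma == c & mb == c), numeric(1))
  inter <- matrix(0, K, K)
  conn <- matrix(0, K, K)
  connectors <- if (is.null(hubs)) integer(0) else
    hubs$node[hubs$hub_class == "connector"]
  cross <- which(ma != mb)
  for (e in cross) {
    a <- ma[e]; b <- mb[e]
    inter[a, b] <- inter[a, b] + 1
    inter[b, a] <- inter[b, a] + 1
    if (ed$i[e] %in% connectors || ed$j[e] %in% connectors) {
      conn[a, b] <- conn[a, b] + 1
      conn[b, a] <- conn[b, a] + 1
    }
  }
  list(intra = intra, inter = inter, connector_inter = conn)
}

#' Group comparison of modular network topology
#'
#' For every module of the reference scheme and each of four nodal
#' metrics (binary degree, participation coefficient, weighted
#' betweenness centrality with lengths 1/w, within-module degree
#' z-score), each subject contributes the mean of that metric over the
#' module's nodes. Groups are compared per module x metric with a
#' permutation t-test (pooled t, subject relabelling, two-sided, +1
#' corrected), and Benjamini-Hochberg q-values are computed across all
#' module x metric tests.
#'
#' @param groupA,groupB [cohort()] objects.
#' @param reference a [partition()].
#' @param n_perm label permutations (default 1000).
#' @param seed RNG seed.
#' @return Data frame with columns `module`, `metric`, `mean_a`,
#'   `mean_b`, `t`, `p`, `q`.
#' @export
compare_modular_topology <- function(groupA, groupB, reference,
                                     n_perm = 1000, seed = NULL) {
  m <- reference$assignment
  K <- max(m)
  subject_module_metrics <- function(cm) {
    W <- cm$weights
    g <- as_weighted_graph(W)
    btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    vals <- cbind(degree = binary_degree(W),
                  pc = participation_coefficient(W, m),
                  betweenness = as.numeric(btw),
                  z_within = within_module_z(W, m))
    t(vapply(seq_len(K), function(c) colMeans(vals[m == c, , drop = FALSE]),
             numeric(4)))  # K x 4
  }
  XA <- lapply(groupA$subjects, subject_module_metrics)
  XB <- lapply(groupB$subjects, subject_module_metrics)
  nA <- length(XA)
  nB <- length(XB)
  metrics <- c("degree", "pc", "betweenness", "z_within")
  rows <- list()
  with_seed(seed, {
    perms <- lapply(seq_len(n_perm), function(r) sample.int(nA + nB))
    for (c in seq_len(K)) {
      for (j in seq_along(metrics)) {
        x <- c(vapply(XA, function(M) M[c, j], numeric(1)),
               vapply(XB, function(M) M[c, j], numeric(1)))
        t_obs <- pooled_t(x[seq_len(nA)], x[nA + seq_len(nB)])
        t_null <- vapply(perms, function(p) {
          pooled_t(x[p[seq_len(nA)]], x[p[nA + seq_len(nB)]])
        }, numeric(1))
        p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          module = c, metric = metrics[j],
          mean_a = mean(x[seq_len(nA)]), mean_b = mean(x[nA + seq_len(nB)]),
          t = t_obs, p = p, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# Pooled-variance two-sample t statistic (variance floored to keep the
# statistic finite for degenerate samples).
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (d == 0) return(0)
    sp2 <- 1e-24
  }
  d / sqrt(sp2 * (1 / na + 1 / nb))
}
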