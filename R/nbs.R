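# Stack both cohorts' upper-triangle edge weights into one
# subjects x edges matrix over the tested edge universe (edges nonzero
# in at least one subject of either group).
edge_design <- function(cohortA, cohortB) {
  n <- nrow(cohortA$subjects[[1]]$weights)
  if (n != nrow(cohortB$subjects[[1]]$weights))
    stopf("cohorts use different atlas sizes")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  grab <- function(ch) t(vapply(ch$subjects,
                                function(s) s$weights[ut], numeric(nrow(ut))))
  XA <- grab(cohortA)
  XB <- grab(cohortB)
  X <- rbind(XA, XB)
  tested <- colSums(X > 0) > 0
  list(X = X[, tested, drop = FALSE], ut = ut[tested, , drop = FALSE],
       n_nodes = n, nA = nrow(XA), nB = nrow(XB))
}

# Two-sample t per column of X, group A rows idxA vs group B rows
# idxB; pooled variance by default, Welch when welch = TRUE. Positive
# t means larger mean in group B. A tiny variance floor keeps the
# statistic finite when both groups are constant but unequal; equal
# constant groups give t = 0.
col_pooled_t <- function(X, idxA, idxB, floor = 1e-24, welch = FALSE) {
  nA <- length(idxA); nB <- length(idxB)
  XA <- X[idxA, , drop = FALSE]
  XB <- X[idxB, , drop = FALSE]
  mA <- colMeans(XA)
  mB <- colMeans(XB)
  vA <- (colSums(XA^2) - nA * mA^2) / (nA - 1)
  vB <- (colSums(XB^2) - nB * mB^2) / (nB - 1)
  if (welch) {
    se2 <- pmax(vA / nA + vB / nB, floor)
    return((mB - mA) / sqrt(se2))
  }
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  sp2 <- pmax(sp2, floor)  # equal constant groups: numerator 0 -> t = 0
  (mB - mA) / sqrt(sp2 * (1 / nA + 1 / nB))
}

#' Edgewise two-sample t-map
#'
#' Pooled-variance two-sample t statistic for every upper-triangle
#' edge present (nonzero) in at least one subject of either cohort.
#' Positive t means the edge is stronger in `cohortB`; untested edges
#' are `NaN`.
#'
#' @param cohortA,cohortB [cohort()] objects (>= 2 subjects each) over
#'   the same atlas.
#' @param welch use the Welch (unequal-variance) statistic instead of
#'   the pooled default.
#' @return N x N symmetric matrix of t statistics (`NaN` = untested).
#' @export
edgewise_tmap <- function(cohortA, cohortB, welch = FALSE) {
  if (length(cohortA$subjects) < 2 || length(cohortB$subjects) < 2)
    stopf("each cohort needs at least 2 subjects")
  d <- edge_design(cohortA, cohortB)
  t_vec <- col_pooled_t(d$X, seq_len(d$nA), d$nA + seq_len(d$nB),
                        welch = welch)
  T <- matrix(NaN, d$n_nodes, d$n_nodes)
  T[d$ut] <- t_vec
  T[d$ut[, 2:1, drop = FALSE]] <- t_vec
  diag(T) <- 0
  T
}

#' Supra-threshold connected components
#'
#' Edges with `|t|` above the primary threshold form a graph; its
#' connected components (with their edge counts, the NBS "extent") are
#' the candidate subnetworks for permutation testing.
#'
#' @param t_map t-statistic matrix from [edgewise_tmap()] (`NaN`
#'   entries are ignored).
#' @param t_thresh primary threshold (> 0), default 2.1.
#' @return List of components, each a data frame (`i`, `j`, `t`)
#'   with attribute `extent`; ordered by decreasing extent. Empty list
#'   when no edge survives.
#' @export
supra_components <- function(t_map, t_thresh = 2.1) {
  if (t_thresh <= 0) stopf("t_thresh must be > 0")
  n <- nrow(t_map)
  idx <- which(upper.tri(t_map) & is.finite(t_map) & abs(t_map) > t_thresh,
               arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  comp <- igraph::components(g)$membership
  edge_comp <- comp[idx[, 1]]
  out <- lapply(unique(edge_comp), function(cc) {
    e <- idx[edge_comp == cc, , drop = FALSE]
    df <- data.frame(i = e[, 1], j = e[, 2], t = t_map[e])
    attr(df, "extent") <- nrow(df)
    df
  })
  out[order(vapply(out, nrow, integer(1)), decreasing = TRUE)]
}

#' Network-based statistic (NBS) permutation test
#'
#' Two-sided NBS: the edgewise |t| map is thresholded at `t_thresh`
#' and the extent (edge count) of each supra-threshold connected
#' component is compared against the permutation null of the maximum
#' component extent under random relabelling of subjects to groups
#' (group sizes preserved). The FWER-corrected p-value of a component
#' of extent s is `(1 + #\{perm max >= s\}) / (1 + n_perm)`. Because
#' thresholding uses |t|, one significant component may mix edges with
#' increased and decreased connectivity; per-edge signs are recorded
#' from the t sign (positive = increase in `cohortB`).
#'
#' @param cohortA,cohortB [cohort()] objects over the same atlas.
#' @param t_thresh primary t threshold (default 2.1).
#' @param n_perm number of permutations (>= 100; default 5000).
#' @param seed RNG seed for the permutations.
#' @param welch use the Welch statistic instead of the pooled default.
#' @return An `nbs_result` list: `t_map`, `primary_threshold`,
#'   `components` (each with per-edge `sign`), `extent`, `p_fwer`,
#'   `sign_map`, `null_max` (permutation distribution), `n_perm`.
#' @export
nbs_test <- function(cohortA, cohortB, t_thresh = 2.1, n_perm = 5000,
                     seed = NULL, welch = FALSE) {
  if (n_perm < 100) stopf("n_perm must be >= 100 for interpretable p-values")
  if (t_thresh <= 0) stopf("t_thresh must be > 0")
  d <- edge_design(cohortA, cohortB)
  nA <- d$nA; nB <- d$nB
  t_obs <- col_pooled_t(d$X, seq_len(nA), nA + seq_len(nB), welch = welch)
  T <- matrix(NaN, d$n_nodes, d$n_nodes)
  T[d$ut] <- t_obs
  T[d$ut[, 2:1, drop = FALSE]] <- t_obs
  diag(T) <- 0
  comps <- supra_components(T, t_thresh)

  null_max <- integer(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      p <- sample.int(nA + nB)
      t_perm <- col_pooled_t(d$X, p[seq_len(nA)], p[nA + seq_len(nB)],
                             welch = welch)
      supra <- which(abs(t_perm) > t_thresh)
      null_max[r] <- max_component_extent(d$ut[supra, 1], d$ut[supra, 2],
                                          d$n_nodes)
    }
  })

  extent <- vapply(comps, nrow, integer(1))
  p_fwer <- vapply(extent, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                   numeric(1))
  comps <- lapply(comps, function(df) {
    df$sign <- ifelse(df$t > 0, "increase", "decrease")
    df
  })
  sign_map <- matrix(NA_character_, d$n_nodes, d$n_nodes)
  sign_map[d$ut] <- ifelse(t_obs > 0, "increase",
                           ifelse(t_obs < 0, "decrease", NA))
  sign_map[d$ut[, 2:1, drop = FALSE]] <- sign_map[d$ut]
  structure(list(t_map = T, primary_threshold = t_thresh,
                 components = comps, extent = extent, p_fwer = p_fwer,
                 sign_map = sign_map, null_max = null_max, n_perm = n_perm,
                 group_labels = c(cohortA$group_label, cohortB$group_label)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s vs %s, |t| > %.2f, %d permutations\n",
              x$group_labels[1], x$group_labels[2], x$primary_threshold,
              x$n_perm))
  if (length(x$components) == 0) {
    cat("  no supra-threshold component\n")
  } else {
    for (k in seq_along(x$components)) {
      df <- x$components[[k]]
      cat(sprintf("  component %d: %d edges (%d increases, %d decreases), p_fwer = %.4f\n",
                  k, nrow(df), sum(df$sign == "increase"),
                  sum(df$sign == "decrease"), x$p_fwer[k]))
    }
  }
  invisible(x)
}
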