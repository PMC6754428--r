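#' Topology specification for synthetic connectomes
#'
#' Describes the planted structure of a simulated structural connectome:
#' a modular block model (within/between module edge probabilities and
#' mean weights), a set of hub nodes whose incident edges are scaled up,
#' and a rich-club core of pairwise-connected nodes at the top weight
#' scale. Per-edge weights are truncated-Gaussian around the block mean.
#'
#' The defaults emulate a 90-region whole-brain parcellation organised
#' into seven communities with about a dozen high-efficiency hubs and a
#' ten-node densely interconnected core, at a realistic overall density
#' (roughly 15-25 percent of possible connections).
#'
#' @param n_regions number of regions (default 90).
#' @param partition_truth integer vector of module ids (1..K) per node;
#'   default: seven contiguous blocks of near-equal size.
#' @param p_within,p_between Bernoulli edge probabilities inside and
#'   between modules.
#' @param w_within,w_between mean edge weights inside and between
#'   modules (arbitrary connectivity-probability units).
#' @param hub_nodes node indices acting as hubs; their incident edges
#'   are both denser (presence probability at least `p_hub`) and
#'   stronger (weights multiplied by `m_hub`), as in empirical
#'   connectome hubs which combine high degree with high strength.
#' @param m_hub hub weight multiplier (> 1).
#' @param p_hub minimum presence probability of hub-incident edges
#'   (default 0.9).
#' @param richclub_nodes node indices forming a dense core: all pairs
#'   among them are connected at the hub weight scale.
#' @param noise_sd standard deviation of the Gaussian weight noise
#'   (truncated at zero).
#' @param seed master seed used when a cohort is generated.
#' @return A `topology_spec` list.
#' @export
topology_spec <- function(n_regions = 90,
                          partition_truth = NULL,
                          p_within = 0.7, p_between = 0.12,
                          w_within = 1.0, w_between = 0.5,
                          hub_nodes = NULL, m_hub = 2, p_hub = 0.9,
                          richclub_nodes = NULL,
                          noise_sd = 0.2, seed = 1L) {
  if (n_regions < 2) stopf("n_regions must be >= 2")
  if (is.null(partition_truth)) {
    k <- min(7L, n_regions)
    partition_truth <- sort(rep_len(seq_len(k), n_regions))
  }
  partition_truth <- as.integer(partition_truth)
  if (length(partition_truth) != n_regions)
    stopf("partition_truth must assign all %d regions", n_regions)
  if (is.null(hub_nodes)) {
    n_hub <- min(13L, n_regions)
    hub_nodes <- unique(round(seq(1, n_regions, length.out = n_hub)))
  }
  if (is.null(richclub_nodes))
    richclub_nodes <- hub_nodes[seq_len(min(10L, length(hub_nodes)))]
  hub_nodes <- as.integer(hub_nodes)
  richclub_nodes <- as.integer(richclub_nodes)
  if (any(c(p_within, p_between, p_hub) < 0) ||
      any(c(p_within, p_between, p_hub) > 1))
    stopf("edge probabilities must be in [0, 1]")
  if (any(c(w_within, w_between) < 0)) stopf("mean weights must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(hub_nodes) && (min(hub_nodes) < 1 || max(hub_nodes) > n_regions))
    stopf("hub_nodes outside region range")
  if (length(richclub_nodes) &&
      (min(richclub_nodes) < 1 || max(richclub_nodes) > n_regions))
    stopf("richclub_nodes outside region range")
  structure(list(n_regions = as.integer(n_regions),
                 partition_truth = partition_truth,
                 p_within = p_within, p_between = p_between,
                 w_within = w_within, w_between = w_between,
                 hub_nodes = hub_nodes, m_hub = m_hub, p_hub = p_hub,
                 richclub_nodes = richclub_nodes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "topology_spec")
}

#' Planted group-difference specification
#'
#' A connected set of edges whose weights are shifted (up or down) in
#' one group, emulating a connected component of altered structural
#' connectivity containing both increases and decreases.
#'
#' @param edge_set two-column matrix (or data frame) of node pairs
#'   (i < j) forming a connected undirected subgraph.
#' @param delta numeric vector of signed weight shifts, one per edge
#'   (recycled if scalar).
#' @param applies_to group label receiving the shift (default `"B"`).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(edge_set, delta, applies_to = "B") {
  edge_set <- as.matrix(edge_set)
  if (ncol(edge_set) != 2) stopf("edge_set must have two columns")
  storage.mode(edge_set) <- "integer"
  flip <- edge_set[, 1] > edge_set[, 2]
  edge_set[flip, ] <- edge_set[flip, 2:1]
  if (any(edge_set[, 1] == edge_set[, 2])) stopf("self-loop in edge_set")
  delta <- rep_len(as.numeric(delta), nrow(edge_set))
  if (nrow(edge_set) > 0) {
    g <- igraph::graph_from_edgelist(edge_set, directed = FALSE)
    used <- sort(unique(as.vector(edge_set)))
    sub <- igraph::induced_subgraph(g, used)
    if (igraph::components(sub)$no != 1)
      stopf("effect edge_set must form a connected subgraph")
  }
  structure(list(edge_set = edge_set, delta = delta,
                 applies_to = applies_to),
            class = "effect_spec")
}

#' Default planted effect: a 71-edge connected component
#'
#' Builds a connected subgraph of 71 edges over a block of regions, with
#' 39 negative and 32 positive weight shifts of magnitude
#' `delta_magnitude` — the shape of a topologically extended,
#' mixed-sign group difference. A spanning tree over 30 nodes (29
#' edges) is densified with 42 further within-set edges.
#'
#' @param n_regions region count of the target topology (>= 30).
#' @param delta_magnitude absolute weight shift per edge.
#' @param applies_to group label receiving the shift.
#' @return An [effect_spec()] with 71 edges.
#' @export
default_effect_spec <- function(n_regions = 90, delta_magnitude = 0.3,
                                applies_to = "B") {
  if (n_regions < 30) stopf("need at least 30 regions")
  nodes <- seq_len(30L)
  tree <- cbind(nodes[-1] %/% 2L + nodes[-1] %% 2L, nodes[-1])  # binary tree
  extra <- list()
  k <- 0L
  for (gap in 2:6) {
    for (i in nodes) {
      j <- i + gap
      if (j <= 30L && k < 42L &&
          !any(tree[, 1] == min(i, j) & tree[, 2] == max(i, j))) {
        k <- k + 1L
        extra[[k]] <- c(min(i, j), max(i, j))
      }
    }
    if (k >= 42L) break
  }
  edges <- rbind(tree, do.call(rbind, extra[seq_len(42L)]))
  stopifnot(nrow(edges) == 71L)
  effect_spec(edges, delta = c(rep(-delta_magnitude, 39),
                               rep(delta_magnitude, 32)),
              applies_to = applies_to)
}

#' Planted covariate relation
#'
#' Specifies a linear relation between a clinical score and the nodal
#' efficiency of one region, with age and gender as planted confounds.
#' The slope applies to the cohort-standardised (z-scored) nodal
#' efficiency, so the generating partial correlation is
#' `slope / sqrt(slope^2 + noise_sd^2)` by construction.
#'
#' @param score_name score column name (default `"fsiq"`).
#' @param target_node region whose nodal efficiency drives the score.
#' @param slope score change per SD of nodal efficiency.
#' @param intercept baseline score.
#' @param confound_slopes named numeric vector with elements `age` and
#'   `gender` (gender coded 0 = M, 1 = F).
#' @param noise_sd residual score noise SD.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(score_name = "fsiq", target_node = 5L,
                           slope = 0.8, intercept = 100,
                           confound_slopes = c(age = 1, gender = 2),
                           noise_sd = 0.6) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(score_name = score_name,
                 target_node = as.integer(target_node),
                 slope = slope, intercept = intercept,
                 confound_slopes = confound_slopes,
                 noise_sd = noise_sd),
            class = "covariate_spec")
}

# Truncated-at-zero Gaussian deviates by inverse-CDF (vectorised).
rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd <= 0) return(pmax(rep_len(mean, n), 0))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Generate one synthetic connectome
#'
#' Draws a symmetric nonnegative weighted matrix from a
#' [topology_spec()]: block-model Bernoulli edges, truncated-Gaussian
#' weights around the block mean, hub-incident edges multiplied by
#' `m_hub`, and the rich-club core fully connected at the top weight
#' scale (`m_hub * w_within`).
#'
#' @param spec a [topology_spec()].
#' @param subject_seed integer seed controlling this subject's draw.
#' @param atlas optional [region_atlas()]; a synthetic one is built if
#'   omitted.
#' @param subject_id subject identifier.
#' @param presence optional logical vector over the upper-triangle
#'   pairs (row-major order of `which(upper.tri(...))`) fixing the
#'   edge topology; when `NULL` the topology is drawn per subject.
#'   [generate_cohorts()] uses this to give all subjects of a study a
#'   shared structural backbone.
#' @return A [connectome()].
#' @export
generate_connectome <- function(spec, subject_seed, atlas = NULL,
                                subject_id = paste0("S", subject_seed),
                                presence = NULL) {
  n <- spec$n_regions
  if (is.null(atlas))
    atlas <- synthetic_atlas(n, seed = derive_seed(spec$seed, 777))
  with_seed(subject_seed, {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    mu <- block_weight_means(spec, ut)
    present <- if (is.null(presence)) {
      stats::runif(nrow(ut)) < edge_probabilities(spec, ut)
    } else presence
    w <- numeric(nrow(ut))
    w[present] <- rtrunc_norm_pos(sum(present), mu[present], spec$noise_sd)
    W[ut] <- w
    W[cbind(ut[, 2], ut[, 1])] <- w
    connectome(W, atlas, subject_id)
  })
}

# Per-pair Bernoulli presence probabilities: block model with a density
# floor on hub-incident pairs (applied only where the block probability
# is already positive).
edge_probabilities <- function(spec, ut) {
  same <- spec$partition_truth[ut[, 1]] == spec$partition_truth[ut[, 2]]
  p <- ifelse(same, spec$p_within, spec$p_between)
  is_hub_edge <- (ut[, 1] %in% spec$hub_nodes) |
    (ut[, 2] %in% spec$hub_nodes)
  dense <- is_hub_edge & p > 0
  p[dense] <- pmax(p[dense], spec$p_hub %||% 0.9)
  # the rich-club core is always wired
  core <- (ut[, 1] %in% spec$richclub_nodes) &
    (ut[, 2] %in% spec$richclub_nodes)
  p[core & p > 0] <- 1
  p
}

# Per-pair mean weights: block means, hub multiplier, rich-club core at
# the top weight scale.
block_weight_means <- function(spec, ut) {
  same <- spec$partition_truth[ut[, 1]] == spec$partition_truth[ut[, 2]]
  mu <- ifelse(same, spec$w_within, spec$w_between)
  is_hub_edge <- (ut[, 1] %in% spec$hub_nodes) |
    (ut[, 2] %in% spec$hub_nodes)
  mu[is_hub_edge] <- mu[is_hub_edge] * spec$m_hub
  core <- (ut[, 1] %in% spec$richclub_nodes) &
    (ut[, 2] %in% spec$richclub_nodes)
  mu[core] <- spec$m_hub * spec$w_within
  mu
}

#' Generate a two-group synthetic study
#'
#' Produces two cohorts of `n_per_group` subjects from a shared
#' [topology_spec()]. By default all subjects share one structural
#' backbone (the edge topology is drawn once from the study seed), as
#' empirical cohorts show high intra-group consistency of structural
#' connectivity; per-subject variability enters through the weight
#' noise. Edges of the planted effect are guaranteed present in the
#' backbone (a weight decrease needs an existing connection), in both
#' groups. Subjects of the group named by `effect$applies_to` then
#' have the planted edge shifts added to their realised weights
#' (clamped at zero). Covariates (age, gender, and the planted score)
#' are drawn per subject; the score follows the [covariate_spec()]
#' linear model on the subject's realised nodal efficiency of the
#' target node, with age/gender contributions and Gaussian noise.
#' Per-subject seeds are spawned from `spec$seed` by fixed offsets, so
#' the study is reproducible subject by subject.
#'
#' @param spec a [topology_spec()].
#' @param effect an [effect_spec()] or `NULL` for no group difference.
#' @param cov a [covariate_spec()] or `NULL` for no planted score.
#' @param n_per_group subjects per group (default 15).
#' @param group_labels character vector of length 2, default
#'   `c("A", "B")`.
#' @param shared_topology draw one edge topology for the whole study
#'   (default) rather than independently per subject.
#' @return List with elements `A` and `B`, each a [cohort()], plus
#'   `atlas`.
#' @export
generate_cohorts <- function(spec, effect = NULL, cov = NULL,
                             n_per_group = 15,
                             group_labels = c("A", "B"),
                             shared_topology = TRUE) {
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  n <- spec$n_regions
  if (!is.null(effect) && nrow(effect$edge_set) > 0 &&
      max(effect$edge_set) > n)
    stopf("effect edges outside region range")
  if (!is.null(cov) && (cov$target_node < 1 || cov$target_node > n))
    stopf("covariate target node outside region range")
  atlas <- synthetic_atlas(n, seed = derive_seed(spec$seed, 777))
  presence <- NULL
  if (shared_topology) {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    presence <- with_seed(derive_seed(spec$seed, 888L),
                          stats::runif(nrow(ut)) < edge_probabilities(spec, ut))
    if (!is.null(effect) && nrow(effect$edge_set) > 0) {
      keys <- (effect$edge_set[, 2] - 1L) * n + effect$edge_set[, 1]
      presence[match(keys, (ut[, 2] - 1L) * n + ut[, 1])] <- TRUE
    }
  }

  make_group <- function(label, grp_index) {
    subs <- vector("list", n_per_group)
    e_target <- numeric(n_per_group)
    for (s in seq_len(n_per_group)) {
      sseed <- derive_seed(spec$seed, grp_index * 10000L + s)
      id <- sprintf("%s%02d", label, s)
      cm <- generate_connectome(spec, sseed, atlas = atlas, subject_id = id,
                                presence = presence)
      if (!is.null(effect) && identical(label, effect$applies_to) &&
          nrow(effect$edge_set) > 0) {
        W <- cm$weights
        idx <- effect$edge_set
        W[idx] <- pmax(W[idx] + effect$delta, 0)
        W[idx[, 2:1, drop = FALSE]] <- W[idx]
        cm <- connectome(W, atlas, id)
      }
      subs[[s]] <- cm
      if (!is.null(cov))
        e_target[s] <- nodal_efficiency(cm)[cov$target_node]
    }
    covdf <- with_seed(derive_seed(spec$seed, grp_index * 10000L + 5000L), {
      age <- pmin(pmax(round(stats::rnorm(n_per_group, 15.5, 1.5), 1), 12), 19)
      gender <- rep_len(c("M", "F"), n_per_group)
      df <- data.frame(subject_id = vapply(subs, `[[`, character(1),
                                           "subject_id"),
                       group = label, age = age, gender = gender,
                       stringsAsFactors = FALSE)
      if (!is.null(cov)) {
        ez <- if (stats::sd(e_target) > 0) {
          (e_target - mean(e_target)) / stats::sd(e_target)
        } else rep(0, n_per_group)
        g01 <- as.numeric(gender == "F")
        df[[cov$score_name]] <- cov$intercept + cov$slope * ez +
          cov$confound_slopes[["age"]] * age +
          cov$confound_slopes[["gender"]] * g01 +
          stats::rnorm(n_per_group, 0, cov$noise_sd)
      }
      df
    })
    cohort(label, subs, covdf)
  }

  list(A = make_group(group_labels[1], 1L),
       B = make_group(group_labels[2], 2L),
       atlas = atlas)
}

#' Write a simulated study to disk in the package's file formats
#'
#' Emits one adjacency TSV per subject under `dir/subjects/`, the atlas
#' TSV, and a combined covariates TSV — the same dialects
#' [read_connectome()], [read_atlas()] and [read_covariates()] consume.
#'
#' @param study result of [generate_cohorts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  subdir <- file.path(dir, "subjects")
  dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
  for (ch in list(study$A, study$B)) {
    for (s in ch$subjects)
      write_connectome(s, file.path(subdir, paste0(s$subject_id, ".tsv")))
  }
  write_atlas(study$atlas, file.path(dir, "atlas.tsv"))
  cov <- rbind(study$A$covariates, study$B$covariates)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
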