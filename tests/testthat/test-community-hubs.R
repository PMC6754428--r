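two_triangles <- function() {
  edge_connectome(6, cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6), 1))
}

test_that("modularity matches hand values and the igraph cross-check", {
  tt <- two_triangles()
  expect_equal(modularity_q(tt, rep(1, 6)), 0)
  expect_equal(modularity_q(tt, rep(1:2, each = 3)), 0.5)

  set.seed(14)
  for (rep in 1:20) {
    W <- random_weight_matrix(9, 0.5)
    m <- sample(1:3, 9, replace = TRUE)
    g <- structnet:::as_weighted_graph(W)
    expect_equal(modularity_q(W, m),
                 igraph::modularity(g, m, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain_best recovers planted structure and is deterministic", {
  tt <- two_triangles()
  p <- louvain_best(tt, n_restarts = 25, seed = 3)
  expect_equal(p$q, 0.5)
  expect_equal(p$n_modules, 2)
  expect_equal(p$assignment, rep(1:2, each = 3))

  clique <- connectome({
    W <- matrix(1, 5, 5); diag(W) <- 0; W
  }, flat_atlas(5))
  pc <- louvain_best(clique, n_restarts = 10, seed = 1)
  expect_lte(pc$q, 0)
  expect_equal(pc$n_modules, 1)

  p2 <- louvain_best(tt, n_restarts = 25, seed = 3)
  expect_identical(p$assignment, p2$assignment)
  expect_error(louvain_best(matrix(0, 4, 4)), "all-zero")
})

test_that("louvain_best attains the exhaustive modularity maximum on small graphs", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(4:7, 1)
    W <- random_weight_matrix(n, runif(1, 0.4, 0.9))
    if (max(W) == 0) next
    p <- louvain_best(W, n_restarts = 40, seed = rep)
    expect_equal(p$q, oracle_max_modularity(W), tolerance = 1e-10)
  }
})

test_that("hub flags from normalised efficiency follow the mean-plus-SD rule", {
  e <- c(1, 1, 1, 1, 2)
  flags <- hubs_by_efficiency(e)
  expect_equal(which(flags), 5)
  norm <- attr(flags, "e_nodal_norm")
  expect_equal(norm[5], 2 / 1.2)
  expect_gt(norm[5], 1 + sd(norm))

  expect_equal(sum(hubs_by_efficiency(rep(3, 6))), 0)
  expect_identical(as.logical(hubs_by_efficiency(e)),
                   as.logical(hubs_by_efficiency(10 * e)))
  expect_error(hubs_by_efficiency(rep(0, 4)), "zero")
})

test_that("hub taxonomy gates on within-module z then splits on PC at 0.3", {
  # module 1: star centre (node 1) with internal links only -> provincial;
  # module 2: star centre (node 7) with half its links into module 1 ->
  # connector
  edges <- rbind(
    cbind(1, 2:6, 1),                 # node 1: 5 internal links
    cbind(7, 8:10, 1),                # node 7: 3 internal links
    cbind(7, 2:4, 1))                 # node 7: 3 links into module 1
  cm <- edge_connectome(10, edges)
  m <- c(rep(1, 6), rep(2, 4))
  hubs <- classify_hubs(cm, m)
  expect_equal(hubs$hub_class[1], "provincial")
  expect_equal(hubs$pc[1], 0)
  expect_equal(hubs$hub_class[7], "connector")
  expect_equal(hubs$pc[7], 0.5)
  expect_true(all(hubs$hub_class[c(2:6, 8:10)] == "none"))
})

test_that("reference partition is taken from the more coherent group", {
  spec <- topology_spec(n_regions = 24, partition_truth = rep(1:3, each = 8),
                        p_within = 0.9, p_between = 0.05, noise_sd = 0.1,
                        hub_nodes = integer(0), richclub_nodes = integer(0),
                        seed = 31)
  st <- generate_cohorts(spec, NULL, NULL, n_per_group = 4)
  # degrade group B: replace its subjects with unstructured graphs
  atlas <- st$atlas
  set.seed(99)
  noisy <- lapply(1:4, function(s)
    connectome(random_weight_matrix(24, 0.35), atlas, sprintf("B%02d", s)))
  st$B <- cohort("B", noisy, st$B$covariates)
  sel <- select_reference_partition(st$A, st$B, n_restarts = 30,
                                    n_restarts_subject = 15, seed = 2)
  expect_equal(sel$selected, "A")
  expect_gt(sel$goodness[["A"]], sel$goodness[["B"]])
  # coherent group's goodness is high (subjects share the planted modules)
  expect_gt(sel$goodness[["A"]], 0.8)

  sel2 <- select_reference_partition(st$A, st$B, n_restarts = 30,
                                     n_restarts_subject = 15, seed = 2)
  expect_identical(sel2$reference$assignment, sel$reference$assignment)
})

test_that("identical subjects give goodness-of-fit exactly 1", {
  spec <- topology_spec(n_regions = 12, partition_truth = rep(1:2, each = 6),
                        p_within = 1, p_between = 0, noise_sd = 0,
                        hub_nodes = integer(0), richclub_nodes = integer(0),
                        seed = 6)
  cm <- generate_connectome(spec, 1)
  subs <- lapply(1:3, function(s) connectome(cm$weights, cm$atlas,
                                             sprintf("A%02d", s)))
  ch <- cohort("A", subs, data.frame(subject_id = sapply(subs, `[[`,
                                                         "subject_id"),
                                     age = 15, gender = "M"))
  sel <- suppressWarnings(select_reference_partition(ch, ch, n_restarts = 10,
                                                     n_restarts_subject = 10,
                                                     seed = 1))
  expect_equal(unname(sel$goodness), c(1, 1))
})

test_that("modular fingerprints count intra/inter edges with conservation", {
  cm <- edge_connectome(4, cbind(c(1, 3, 1), c(2, 4, 3), 1))
  ref <- partition(c(1, 1, 2, 2))
  fp <- modular_fingerprint(cm, ref)
  expect_equal(fp$intra, c(1, 1))
  expect_equal(fp$inter[1, 2], 1)
  expect_true(isSymmetric(fp$inter))
  expect_true(all(fp$connector_inter == 0))  # no hub table given

  # conservation on random instances: sum intra + upper-tri inter = E
  set.seed(41)
  for (rep in 1:20) {
    cmr <- random_connectome(12, 0.5)
    m <- sample(1:3, 12, replace = TRUE)
    fpr <- modular_fingerprint(cmr, partition(m))
    expect_equal(sum(fpr$intra) + sum(fpr$inter[upper.tri(fpr$inter)]),
                 nrow(upper_edges(cmr$weights)))
    # connector-restricted counts never exceed the full inter counts
    expect_true(all(fpr$connector_inter <= fpr$inter))
  }
})

test_that("merging two modules pools their intra and inter counts", {
  set.seed(42)
  cm <- random_connectome(10, 0.6)
  m <- c(rep(1, 4), rep(2, 3), rep(3, 3))
  fp <- modular_fingerprint(cm, partition(m))
  m2 <- ifelse(m == 2, 1, m)  # merge modules 1 and 2
  fp2 <- modular_fingerprint(cm, partition(m2))
  expect_equal(fp2$intra[1], fp$intra[1] + fp$intra[2] + fp$inter[1, 2])
})

test_that("modular topology comparison finds a planted degree boost after FDR", {
  spec <- topology_spec(n_regions = 20, partition_truth = rep(1:2, each = 10),
                        p_within = 0.7, p_between = 0.2, noise_sd = 0.1,
                        hub_nodes = integer(0), richclub_nodes = integer(0),
                        seed = 55)
  st <- generate_cohorts(spec, NULL, NULL, n_per_group = 8)
  # boost group B's module-2 internal connectivity: add edges
  st$B <- cohort("B", lapply(st$B$subjects, function(s) {
    W <- s$weights
    block <- 11:20
    miss <- which(W[block, block] == 0 & upper.tri(diag(10)), arr.ind = TRUE)
    add <- miss[seq_len(min(20, nrow(miss))), , drop = FALSE]
    W[cbind(block[add[, 1]], block[add[, 2]])] <- 1
    W[cbind(block[add[, 2]], block[add[, 1]])] <- 1
    connectome(W, s$atlas, s$subject_id)
  }), st$B$covariates)
  ref <- partition(spec$partition_truth)
  cmp <- compare_modular_topology(st$A, st$B, ref, n_perm = 400, seed = 7)
  expect_equal(nrow(cmp), 2 * 4)
  row <- cmp[cmp$module == 2 & cmp$metric == "degree", ]
  expect_lt(row$q, 0.05)
  expect_lt(row$mean_a, row$mean_b)
})
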