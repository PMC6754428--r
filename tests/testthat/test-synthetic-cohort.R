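test_that("generated connectomes satisfy matrix invariants and seed determinism", {
  spec <- topology_spec(n_regions = 20, partition_truth = rep(1:2, each = 10),
                        hub_nodes = c(1, 11), richclub_nodes = c(1, 11),
                        seed = 3)
  a <- generate_connectome(spec, 42)
  b <- generate_connectome(spec, 42)
  expect_identical(a$weights, b$weights)
  expect_true(isSymmetric(unname(a$weights)))
  expect_true(all(diag(a$weights) == 0))
  expect_true(all(a$weights >= 0))
  c2 <- generate_connectome(spec, 43)
  expect_false(identical(a$weights, c2$weights))
})

test_that("degenerate probabilities give the expected limits", {
  # p = 0 everywhere: empty matrix
  spec0 <- topology_spec(n_regions = 10, partition_truth = rep(1:2, each = 5),
                         p_within = 0, p_between = 0, hub_nodes = integer(0),
                         richclub_nodes = integer(0), seed = 1)
  expect_true(all(generate_connectome(spec0, 1)$weights == 0))

  # p_within = 1, p_between = 0, no noise: two uniform cliques
  spec1 <- topology_spec(n_regions = 8, partition_truth = rep(1:2, each = 4),
                         p_within = 1, p_between = 0, noise_sd = 0,
                         hub_nodes = integer(0), richclub_nodes = integer(0),
                         w_within = 1, seed = 1)
  W <- generate_connectome(spec1, 1)$weights
  expect_true(all(W[1:4, 1:4][upper.tri(diag(4))] == 1))
  expect_true(all(W[5:8, 5:8][upper.tri(diag(4))] == 1))
  expect_true(all(W[1:4, 5:8] == 0))

  expect_error(topology_spec(n_regions = 0), "n_regions")
})

test_that("with deterministic blocks the true partition attains the exhaustive modularity maximum", {
  spec <- topology_spec(n_regions = 8, partition_truth = rep(1:2, each = 4),
                        p_within = 1, p_between = 0, noise_sd = 0,
                        hub_nodes = integer(0), richclub_nodes = integer(0),
                        seed = 1)
  W <- generate_connectome(spec, 1)$weights
  q_true <- modularity_q(W, spec$partition_truth)
  expect_equal(q_true, oracle_max_modularity(W))
  expect_equal(q_true, 0.5)  # two disconnected equal cliques
})

test_that("planted hubs occupy the top efficiency ranks at high multiplier", {
  hub_set <- c(3, 13, 23)
  spec <- topology_spec(n_regions = 30, partition_truth = rep(1:3, each = 10),
                        hub_nodes = hub_set, m_hub = 5,
                        richclub_nodes = integer(0), seed = 8)
  hits <- 0L
  for (r in 1:20) {
    e <- nodal_efficiency(generate_connectome(spec, 100 + r))
    top <- order(e, decreasing = TRUE)[seq_along(hub_set)]
    if (setequal(top, hub_set)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("generate_cohorts plants the effect only in the target group and validates ranges", {
  spec <- topology_spec(n_regions = 12, partition_truth = rep(1:2, each = 6),
                        p_within = 1, p_between = 1, noise_sd = 0,
                        hub_nodes = integer(0), richclub_nodes = integer(0),
                        w_within = 1, w_between = 1, seed = 5)
  eff <- effect_spec(cbind(1:3, 2:4), delta = 0.5)
  st <- generate_cohorts(spec, eff, cov = NULL, n_per_group = 3)
  for (s in st$A$subjects) expect_equal(unname(s$weights[1, 2]), 1)
  for (s in st$B$subjects) expect_equal(unname(s$weights[1, 2]), 1.5)
  # untouched edge equal across groups
  expect_equal(st$A$subjects[[1]]$weights[5, 6], st$B$subjects[[1]]$weights[5, 6])
  # decreases clamp at zero
  eff_neg <- effect_spec(cbind(1, 2), delta = -5)
  st2 <- generate_cohorts(spec, eff_neg, NULL, n_per_group = 2)
  expect_equal(unname(st2$B$subjects[[1]]$weights[1, 2]), 0)

  expect_error(generate_cohorts(spec, effect_spec(cbind(1, 99), 1), NULL, 3),
               "region range")
  expect_error(effect_spec(rbind(c(1, 2), c(5, 6)), 1), "connected")
})

test_that("cohort generation is reproducible and covariates are complete", {
  spec <- topology_spec(n_regions = 15, partition_truth = rep(1:3, each = 5),
                        seed = 77)
  s1 <- generate_cohorts(spec, NULL, covariate_spec(target_node = 2),
                         n_per_group = 4)
  s2 <- generate_cohorts(spec, NULL, covariate_spec(target_node = 2),
                         n_per_group = 4)
  expect_identical(s1$A$subjects[[3]]$weights, s2$A$subjects[[3]]$weights)
  expect_identical(s1$B$covariates, s2$B$covariates)
  expect_true(all(c("age", "gender", "fsiq") %in% names(s1$A$covariates)))
  expect_equal(nrow(s1$A$covariates), 4)
})

test_that("a zero covariate slope yields near-zero partial correlation over replicates", {
  spec <- topology_spec(n_regions = 12, partition_truth = rep(1:2, each = 6),
                        seed = 9)
  cv <- covariate_spec(target_node = 3, slope = 0, noise_sd = 1)
  rs <- sapply(1:30, function(r) {
    sp <- spec; sp$seed <- 1000L + r
    st <- generate_cohorts(sp, NULL, cv, n_per_group = 10)
    e <- vapply(st$B$subjects, function(s) nodal_efficiency(s)[3], numeric(1))
    covb <- st$B$covariates
    Z <- data.frame(age = covb$age, gender = as.numeric(covb$gender == "F"))
    partial_correlation(e, covb$fsiq, Z)$r_partial
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("write_study round-trips through the file readers", {
  dir <- tempfile("study")
  spec <- topology_spec(n_regions = 10, partition_truth = rep(1:2, each = 5),
                        seed = 4)
  st <- generate_cohorts(spec, NULL, NULL, n_per_group = 2)
  write_study(st, dir)
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(nrow(atlas), 10)
  cov <- read_covariates(file.path(dir, "covariates.tsv"))
  expect_equal(nrow(cov), 4)
  id <- st$A$subjects[[1]]$subject_id
  cm <- read_connectome(file.path(dir, "subjects", paste0(id, ".tsv")), atlas)
  expect_equal(unname(cm$weights), unname(st$A$subjects[[1]]$weights),
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
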