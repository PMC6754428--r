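test_that("read_connectome validates, symmetrises small asymmetry, rejects large", {
  atlas <- flat_atlas(3)
  f <- withr::local_tempfile(fileext = ".tsv")

  write.table(matrix(0, 3, 3), f, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  cm <- read_connectome(f, atlas)
  expect_true(all(cm$weights == 0))

  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  cm <- read_connectome(f, atlas)
  expect_equal(cm$weights[1, 2], 2)
  expect_equal(cm$weights[2, 1], 2)

  # CSV dialect is sniffed
  write.table(W, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_connectome(f, atlas)$weights[1, 2], 2)

  # asymmetry far beyond tolerance is an error
  W[1, 2] <- 1
  W[2, 1] <- 3
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(f, atlas), "asymmetric")

  # non-square and negative inputs name the problem
  write.table(matrix(0, 2, 3), f, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  expect_error(read_connectome(f, atlas), "square")
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- -1
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(f, atlas), "negative")
})

test_that("symmetrize_directed averages directed probabilities", {
  P <- matrix(0, 3, 3)
  P[1, 2] <- 0.4
  P[2, 1] <- 0.2
  out <- symmetrize_directed(P)
  expect_equal(out[1, 2], 0.3)
  expect_equal(out[2, 1], 0.3)

  S <- random_weight_matrix(5, 0.6)
  expect_equal(symmetrize_directed(S), {
    S2 <- S
    diag(S2) <- 0
    S2
  })
  expect_equal(symmetrize_directed(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(symmetrize_directed(matrix(-1, 2, 2)), "negative")
})

test_that("volume_normalize divides rows by seed-region voxel count", {
  atlas <- region_atlas(data.frame(
    id = 1:3, label = c("a", "b", "c"), hemisphere = "left",
    x = 0, y = 0, z = 0, volume = c(5L, 1L, 1L)))
  P <- matrix(0, 3, 3)
  P[1, 2] <- 10
  out <- volume_normalize(P, atlas)
  expect_equal(out[1, 2], 2)

  atlas1 <- region_atlas(data.frame(
    id = 1:3, label = c("a", "b", "c"), hemisphere = "left",
    x = 0, y = 0, z = 0, volume = 1L))
  expect_equal(volume_normalize(P, atlas1), P)

  expect_error(region_atlas(data.frame(
    id = 1:3, label = c("a", "b", "c"), hemisphere = "left",
    x = 0, y = 0, z = 0, volume = c(0L, 1L, 1L))), "positive")
})

test_that("volume_normalize then symmetrize commutes with uniform volume scaling", {
  set.seed(11)
  P <- matrix(runif(36), 6, 6)
  diag(P) <- 0
  mkatlas <- function(v) region_atlas(data.frame(
    id = 1:6, label = letters[1:6], hemisphere = "left",
    x = 0, y = 0, z = 0, volume = v))
  v <- c(2L, 3L, 4L, 5L, 6L, 7L)
  a <- symmetrize_directed(volume_normalize(P, mkatlas(v)))
  b <- symmetrize_directed(volume_normalize(P, mkatlas(3L * v)))
  expect_equal(a, 3 * b)
})

test_that("threshold_bottom_rank removes floor(fraction * E) weakest links", {
  # 200 nonzero edges -> exactly 2 removed at 1%
  set.seed(5)
  n <- 25
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  pick <- sample(nrow(ut), 200)
  w <- runif(200, 0.1, 1)
  W[ut[pick, ]] <- w
  W[ut[pick, 2:1]] <- w
  cm <- connectome(W, flat_atlas(n))
  thr <- threshold_bottom_rank(cm, 0.01)
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 198)
  # the removed ones are the two weakest
  kept <- upper_edges(thr$weights)$w
  expect_equal(sort(kept), sort(w)[-(1:2)], tolerance = 1e-12)

  # floor to zero: 50 edges at 1% removes nothing
  cm50 <- random_connectome(12, p = 0.75)
  e50 <- upper_edges(cm50$weights)
  frac <- 0.9 / nrow(e50)
  expect_equal(threshold_bottom_rank(cm50, frac)$weights, cm50$weights)
})

test_that("threshold_bottom_rank breaks ties lexicographically and is idempotent", {
  n <- 25
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  W[ut] <- 1
  W[ut[, 2:1]] <- 1  # 300 equal-weight edges
  cm <- connectome(W, flat_atlas(n))
  thr <- threshold_bottom_rank(cm, 0.01)
  removed <- which(cm$weights > 0 & thr$weights == 0 &
                     upper.tri(cm$weights), arr.ind = TRUE)
  removed <- removed[order(removed[, 1], removed[, 2]), , drop = FALSE]
  # lexicographically smallest (i, j): (1,2), (1,3), (1,4)
  expect_equal(unname(removed), cbind(c(1, 1, 1), c(2, 3, 4)))
  # re-applying with a fraction below 1/E removes nothing more
  again <- threshold_bottom_rank(thr, 0.003)
  expect_equal(again$weights, thr$weights)
})

test_that("rescale_by_max yields max 1 and errors on all-zero", {
  cm <- edge_connectome(3, cbind(1, 2:3, c(2, 4)))
  rs <- rescale_by_max(cm)
  expect_equal(max(rs$weights), 1)
  expect_equal(rs$weights[1, 2], 0.5)
  expect_equal(rescale_by_max(rs)$weights, rs$weights)
  expect_error(rescale_by_max(connectome(matrix(0, 3, 3), flat_atlas(3))),
               "all-zero")
})

test_that("group_average is the element-wise mean", {
  atlas <- flat_atlas(3)
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 1
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 3
  cov <- data.frame(subject_id = c("s1", "s2"), age = 15, gender = "M")
  ch <- cohort("g", list(connectome(W1, atlas, "s1"),
                         connectome(W2, atlas, "s2")), cov)
  expect_equal(group_average(ch)$weights[1, 2], 2)
  ch1 <- cohort("g", list(connectome(W1, atlas, "s1")), cov[1, ])
  expect_equal(group_average(ch1)$weights, connectome(W1, atlas)$weights)
})

test_that("preprocessing preserves symmetry and zero diagonal on random inputs", {
  set.seed(21)
  for (rep in 1:10) {
    cm <- random_connectome(12, p = 0.6)
    for (out in list(threshold_bottom_rank(cm, 0.05)$weights,
                     rescale_by_max(cm)$weights,
                     symmetrize_directed(matrix(runif(144), 12, 12)))) {
      expect_true(isSymmetric(unname(out)))
      expect_true(all(diag(out) == 0))
      expect_true(all(out >= 0))
    }
  }
})
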