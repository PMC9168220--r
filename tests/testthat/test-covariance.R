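test_that("structural covariance matches hand-computed Pearson values", {
  M <- cbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 1, 2))
  g <- structural_covariance(M)
  expect_equal(g$weights["a", "b"], brute_pearson(M[, 1], M[, 2]),
               tolerance = 1e-12)
  expect_equal(round(g$weights["a", "b"], 3), 0.982)
  expect_true(isSymmetric(g$weights))
  expect_equal(diag(g$weights), c(a = 0, b = 0, c = 0))
})

test_that("identical columns correlate at one; anticorrelated edges are zeroed", {
  M <- cbind(x = c(1, 5, 3, 2), y = c(1, 5, 3, 2), z = -c(1, 5, 3, 2))
  g <- structural_covariance(M)
  expect_equal(g$weights["x", "y"], 1)
  expect_equal(g$weights["x", "z"], 0)      # excluded negative edge
  expect_equal(g$weights["y", "z"], 0)
  expect_equal(g$retained_fraction, 1 / 3)
})

test_that("zero-variance regions are rejected by name", {
  M <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(structural_covariance(M), "flat")
  expect_error(structural_covariance(matrix(rnorm(4), 2, 2)), "3 subjects")
})

test_that("cross-property covariance is the transpose of the reversed pair before zeroing", {
  set.seed(1)
  M1 <- matrix(rnorm(40), 8, 5)
  M2 <- matrix(rnorm(40), 8, 5)
  W12 <- cor(M1, M2)
  W21 <- cor(M2, M1)
  expect_lt(max(abs(W12 - t(W21))), 1e-12)
  # package result agrees entry-wise with the brute-force oracle
  g <- cross_property_covariance(M1, M2)
  B <- brute_cor_matrix(M1, M2)
  diag(B) <- 0
  B[B < 0] <- 0
  expect_lt(max(abs(g$weights - B)), 1e-12)
  expect_true(g$directed)
})

test_that("a property crossed with itself reduces to the symmetric case with a zeroed diagonal", {
  set.seed(2)
  M <- matrix(rnorm(30), 6, 5)
  g <- cross_property_covariance(M, M)
  expect_equal(diag(g$weights), rep(0, 5))
  expect_true(isSymmetric(unname(g$weights)))
})

test_that("misaligned subjects are rejected", {
  M1 <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("s", 1:4), NULL))
  M2 <- M1[c(2, 1, 3, 4), ]
  expect_error(cross_property_covariance(M1, M2), "not aligned")
})

test_that("density thresholding keeps exactly the strongest edges", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.5, 0.8, 0.3, 0.7, 0.1)
  W <- W + t(W)
  g <- structural_covariance(matrix(rnorm(30), 6, 5))  # placeholder container
  g$weights <- W
  g$directed <- FALSE
  A <- threshold_to_density(g, 0.5)
  expect_equal(sum(A[upper.tri(A)] > 0), 3L)
  expect_setequal(A[upper.tri(A)][A[upper.tri(A)] > 0], c(0.9, 0.8, 0.7))
  # weights preserved, not binarized
  expect_equal(max(A), 0.9)
  # rho = 1 on an all-positive graph returns the graph unchanged
  W2 <- matrix(runif(25, 0.1, 1), 5, 5)
  W2 <- (W2 + t(W2)) / 2
  diag(W2) <- 0
  g$weights <- W2
  expect_equal(threshold_to_density(g, 1), W2, ignore_attr = TRUE)
})

test_that("thresholding matches the exhaustive-sort oracle on random graphs", {
  set.seed(33)
  g <- structural_covariance(matrix(rnorm(60), 10, 6))
  for (rep in 1:25) {
    P <- sample(4:9, 1)
    directed <- runif(1) < 0.5
    W <- if (directed) rand_dir_graph(P, 0.8) else rand_sym_graph(P, 0.8)
    g$weights <- W
    g$directed <- directed
    emax <- if (directed) P * (P - 1) else P * (P - 1) / 2
    npos <- if (directed) sum(W > 0) else sum(W[upper.tri(W)] > 0)
    rho <- 0.4
    k <- round(rho * emax)
    if (k < 1 || k > npos) next
    expect_equal(threshold_to_density(g, rho), brute_threshold(W, k, directed),
                 ignore_attr = TRUE)
  }
})

test_that("ties at the cut are resolved deterministically", {
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.3)
  W <- W + t(W)
  g <- structural_covariance(matrix(rnorm(36), 6, 6))
  g$weights <- W
  g$directed <- FALSE
  A1 <- threshold_to_density(g, 0.4)
  A2 <- threshold_to_density(g, 0.4)
  expect_identical(A1, A2)
  expect_equal(sum(A1[upper.tri(A1)] > 0), 4L)
  # the kept tied edges are the first in (row, column) order
  kept <- which(A1 != 0 & upper.tri(A1), arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
  allt <- which(W == 0.5 & upper.tri(W), arr.ind = TRUE)
  allt <- allt[order(allt[, 1], allt[, 2]), , drop = FALSE]
  expect_equal(unname(kept), unname(allt[1:4, ]))
})

test_that("infeasible densities fail with the maximum feasible density named", {
  M <- cbind(a = c(1, 2, 3, 5), b = c(2, 3, 4, 7), c = -c(1.1, 2, 3.2, 5))
  g <- structural_covariance(M)   # only one positive edge out of three pairs
  expect_error(threshold_to_density(g, 0.9), "maximum feasible density")
})

test_that("the default density grid has 41 points and sweeps are nested", {
  grid <- density_grid()
  expect_length(grid, 41L)
  expect_equal(min(grid), 0.20)
  expect_equal(max(grid), 0.60)
  expect_error(density_grid(0.2, 0.6, 0.007), "divide")
  expect_error(density_grid(0, 0.5), "rho_min")

  set.seed(44)
  for (rep in 1:10) {
    W <- rand_sym_graph(12, 0.95)
    g <- structural_covariance(matrix(rnorm(130), 13, 10))
    g$weights <- W
    g$directed <- FALSE
    adjs <- density_sweep(g, density_grid(0.1, 0.6, 0.05))
    for (k in 2:length(adjs)) {
      prev_edges <- adjs[[k - 1]] > 0
      expect_true(all(adjs[[k]][prev_edges] > 0))  # edge-set nestedness
    }
  }
})

test_that("connectivity detection agrees with igraph and matrix powering", {
  skip_if_not_installed("igraph")
  # path graph and two disjoint triangles
  path <- matrix(0, 4, 4)
  path[cbind(1:3, 2:4)] <- 1
  path <- path + t(path)
  expect_true(is_fully_connected(path))
  twotri <- matrix(0, 6, 6)
  twotri[cbind(c(1, 2, 3), c(2, 3, 1))] <- 1
  twotri[cbind(c(4, 5, 6), c(5, 6, 4))] <- 1
  twotri <- twotri + t(twotri)
  expect_false(is_fully_connected(twotri))

  set.seed(55)
  for (rep in 1:30) {
    A <- rand_sym_graph(10, runif(1, 0.05, 0.4))
    ig <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
    expect_equal(is_fully_connected(A), igraph::is_connected(ig))
    expect_equal(is_fully_connected(A), brute_connected(A))
  }
})

test_that("retained fraction is invariant under a common subject permutation", {
  set.seed(66)
  M1 <- matrix(rnorm(80), 16, 5)
  M2 <- matrix(rnorm(80), 16, 5)
  perm <- sample(16)
  g0 <- cross_property_covariance(M1, M2)
  g1 <- cross_property_covariance(M1[perm, ], M2[perm, ])
  expect_equal(g0$retained_fraction, g1$retained_fraction)
  expect_lt(max(abs(g0$weights - g1$weights)), 1e-12)
})
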