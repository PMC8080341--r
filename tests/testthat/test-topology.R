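# Fixtures used repeatedly: adjacency matrices are weights (correlations);
# path lengths are reciprocals of weights.

path3 <- local({
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 3] <- 1
  m + t(m)
})

complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

star_graph <- function(n) {
  m <- matrix(0, n, n)
  m[1, -1] <- 1
  m + t(m)
}

ring_lattice <- function(n, k) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (offset in seq_len(k / 2)) {
      j <- ((i - 1 + offset) %% n) + 1
      m[i, j] <- m[j, i] <- 1
    }
  }
  m
}

test_that("weighted shortest paths route around weak edges", {
  d <- shortest_path_lengths(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))

  # triangle with one weak (0.25) edge: going around (1 + 1 = 2) beats the
  # direct length 1/0.25 = 4
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 3] <- 1
  tri[1, 3] <- 0.25
  tri <- tri + t(tri)
  d <- shortest_path_lengths(tri)
  expect_equal(d[1, 3], 2)

  # disconnection encoded as Inf
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(iso)[1, 3], Inf)
})

test_that("efficiencies and path length match closed forms", {
  k5 <- complete_graph(5)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(k5), 1)
  expect_equal(characteristic_path_length(k5), 1)
  expect_equal(clustering_coefficient(k5)$mean, 1)

  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(characteristic_path_length(path3), 6 / 5)
  expect_equal(nodal_efficiency(path3), c(3 / 4, 1, 3 / 4))

  s6 <- star_graph(6)
  expect_equal(clustering_coefficient(s6)$mean, 0)
  expect_equal(local_efficiency(s6), 0)

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_warning(lp <- characteristic_path_length(empty), "disconnected")
  expect_equal(lp, Inf)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("L_p is exactly the reciprocal of E_net under the harmonic form", {
  set.seed(21)
  for (rep in 1:5) {
    w <- random_weighted_graph(sample(4:9, 1))
    if (max(w) == 0) next
    expect_equal(characteristic_path_length(w), 1 / global_efficiency(w),
                 tolerance = 1e-12)
  }
})

test_that("arithmetic-mean path length averages connected pairs only", {
  # two components: a unit edge pair and an isolated node
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  expect_equal(characteristic_path_length(m, method = "mean"), 1)
})

test_that("clustering matches brute-force triple enumeration", {
  set.seed(22)
  for (rep in 1:5) {
    w <- random_weighted_graph(5)
    got <- clustering_coefficient(w)
    want <- oracle_clustering(w)
    expect_equal(got$nodal, want$nodal, tolerance = 1e-12)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
  }
})

test_that("local efficiency matches per-node brute-force subgraph efficiency", {
  set.seed(23)
  w <- random_weighted_graph(6)
  expect_equal(local_efficiency(w), oracle_local_efficiency(w),
               tolerance = 1e-12)
})

test_that("betweenness counts shortest paths with even tie splitting", {
  b <- betweenness_centrality(path3)
  expect_equal(unname(b), c(0, 1, 0))

  # 4-cycle, unit weights: opposite pairs have two equal paths, each middle
  # node gets 1/2
  c4 <- matrix(0, 4, 4)
  c4[1, 2] <- c4[2, 3] <- c4[3, 4] <- c4[4, 1] <- 1
  c4 <- c4 + t(c4)
  expect_equal(unname(betweenness_centrality(c4)), rep(0.5, 4))

  set.seed(24)
  w <- random_weighted_graph(7)
  expect_equal(unname(betweenness_centrality(w)), oracle_betweenness(w),
               tolerance = 1e-9)
})

test_that("degree is weighted strength by default, binary on request", {
  k4 <- complete_graph(4)
  expect_equal(node_degree(k4), rep(3, 4))
  expect_equal(node_degree(matrix(0, 3, 3)), rep(0, 3))
  set.seed(25)
  w <- random_weighted_graph(6)
  expect_equal(node_degree(w), rowSums(w))
  expect_equal(node_degree(w, weighted = FALSE), rowSums(w > 0))
})

test_that("degree-preserving surrogates keep every binary degree", {
  set.seed(26)
  w <- random_weighted_graph(12, p_edge = 0.4)
  nul <- random_null_metrics(w, n_null = 8, seed = 3,
                             return_surrogates = TRUE)
  for (surr in nul$surrogates) {
    expect_equal(rowSums(surr > 0), rowSums(w > 0))
    expect_equal(sort(surr[upper.tri(surr)][surr[upper.tri(surr)] > 0]),
                 sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
  }
})

test_that("null normalization is exactly 1 for a rewiring-invariant graph", {
  k6 <- complete_graph(6)
  expect_warning(nul <- random_null_metrics(k6, n_null = 5, seed = 1),
                 "no degree-preserving rewiring")
  expect_equal(nul$C_p_rand, clustering_coefficient(k6)$mean)
  expect_equal(nul$L_p_rand, characteristic_path_length(k6))
  expect_equal(small_world(clustering_coefficient(k6)$mean / nul$C_p_rand,
                           characteristic_path_length(k6) / nul$L_p_rand), 1)
})

test_that("a ring lattice has higher clustering than its random surrogates", {
  rl <- ring_lattice(20, 4)
  nul <- random_null_metrics(rl, n_null = 20, seed = 7)
  gamma <- clustering_coefficient(rl)$mean / nul$C_p_rand
  expect_gt(gamma, 1)
})

test_that("null metrics are reproducible from the seed", {
  set.seed(27)
  w <- random_weighted_graph(10, p_edge = 0.5)
  a <- random_null_metrics(w, n_null = 6, seed = 42)
  b <- random_null_metrics(w, n_null = 6, seed = 42)
  expect_identical(a, b)
})

test_that("small_world is the gamma/lambda ratio and rejects lambda = 0", {
  expect_equal(small_world(2, 1), 2)
  expect_equal(small_world(1.7, 1.7), 1)
  expect_error(small_world(2, 0), "nonzero")
})

test_that("AUC integrates curves over the grid", {
  grid <- sparsity_grid(32)
  expect_equal(auc_over_grid(rep(2, length(grid)), grid), 2 * 0.28)
  expect_equal(auc_over_grid(c(0, 0.5, 1), c(0, 0.5, 1)), 0.5)
  set.seed(28)
  y <- rnorm(length(grid))
  expect_equal(auc_over_grid(y, grid), oracle_auc(y, grid),
               tolerance = 1e-12)
  # rectangle rule is the left Riemann sum
  expect_equal(auc_over_grid(c(1, 3), c(0, 0.5), rule = "rectangle"), 0.5)
  expect_error(auc_over_grid(1, 0.2), "2 points")
  expect_error(auc_over_grid(c(1, Inf), c(0.1, 0.2)), "non-finite")
  expect_error(auc_over_grid(c(1, 2, 3), c(0.1, 0.2)), "differ")
})

test_that("metric pipeline runs the full grid and respects duplicates", {
  set.seed(29)
  ts <- matrix(rnorm(150 * 32), 150, 32)
  cm <- compute_connectivity(ts)
  mc <- suppressWarnings(metric_pipeline(cm, n_null = 0))
  expect_length(mc$grid, 29L)
  expect_equal(mc$grid[1], 0.12)
  expect_identical(dim(mc$nodal$degree), c(29L, 32L))
  expect_true(all(is.finite(mc$auc$network[c("E_net", "E_loc", "L_p",
                                             "C_p")])))
  expect_true(all(is.na(mc$auc$network[c("gamma", "lambda", "sigma")])))
  # identical input twice gives identical AUCs
  mc2 <- suppressWarnings(metric_pipeline(cm, n_null = 0))
  expect_identical(mc$auc, mc2$auc)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(30)
  w <- random_weighted_graph(9, p_edge = 0.5)
  perm <- sample(9)
  wp <- w[perm, perm]
  expect_equal(global_efficiency(w), global_efficiency(wp))
  expect_equal(local_efficiency(w), local_efficiency(wp), tolerance = 1e-12)
  expect_equal(clustering_coefficient(w)$mean,
               clustering_coefficient(wp)$mean, tolerance = 1e-12)
  expect_equal(sort(unname(betweenness_centrality(w))),
               sort(unname(betweenness_centrality(wp))), tolerance = 1e-9)
  expect_equal(characteristic_path_length(w),
               characteristic_path_length(wp), tolerance = 1e-12)
})

test_that("gamma, lambda, sigma obey their definitional identity on the grid", {
  set.seed(31)
  cm <- compute_connectivity(matrix(rnorm(120 * 16), 120, 16))
  grid <- sparsity_grid(16)[1:4]
  mc <- suppressWarnings(metric_pipeline(cm, grid = grid, n_null = 4,
                                         seed = 2))
  expect_equal(mc$network$sigma, mc$network$gamma / mc$network$lambda)
})
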