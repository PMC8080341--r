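# Small helper: wrap a list of symmetric matrices around per-subject noise.
make_paired_mats <- function(n_sub, n_nodes, shift_edge = NULL, shift = 0,
                             sd = 0.05) {
  pre <- post <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    base <- matrix(0, n_nodes, n_nodes)
    base[upper.tri(base)] <- rnorm(n_nodes * (n_nodes - 1) / 2, 0.2, 0.1)
    base <- base + t(base)
    noise <- matrix(0, n_nodes, n_nodes)
    noise[upper.tri(noise)] <- rnorm(n_nodes * (n_nodes - 1) / 2, 0, sd)
    noise <- noise + t(noise)
    pre[[s]] <- base
    post[[s]] <- base + noise
    if (!is.null(shift_edge)) {
      i <- shift_edge[1]
      j <- shift_edge[2]
      post[[s]][i, j] <- post[[s]][j, i] <- post[[s]][i, j] + shift
    }
  }
  list(pre = pre, post = post)
}

test_that("edgewise paired t matches the textbook formula", {
  # 4 subjects, single informative edge, hand-computed
  d <- c(0.50, 0.45, 0.55, 0.50)
  pre <- lapply(1:4, function(s) matrix(0, 3, 3))
  post <- lapply(1:4, function(s) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- d[s]
    m
  })
  res <- edgewise_paired_t(pre, post)
  want_t <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t[1, 2], want_t)
  expect_equal(res$t[2, 1], want_t)
  expect_equal(res$p[1, 2], 2 * pt(-abs(want_t), 3))
  expect_identical(res$df, 3L)
})

test_that("identical sessions give zero t everywhere, zero variance warns", {
  mats <- lapply(1:5, function(s) {
    m <- matrix(rnorm(16), 4, 4)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  res <- edgewise_paired_t(mats, mats)
  expect_true(all(res$t == 0))

  # constant nonzero difference: t = Inf, flagged suprathreshold
  shifted <- lapply(mats, function(m) {
    m[1, 2] <- m[2, 1] <- m[1, 2] + 0.5
    m
  })
  expect_warning(res <- edgewise_paired_t(mats, shifted), "zero-variance")
  expect_identical(res$t[1, 2], Inf)
  expect_equal(res$p[1, 2], 0)
})

test_that("a constant-shifted edge attains the largest |t|", {
  set.seed(51)
  mats <- make_paired_mats(8, 10, shift_edge = c(2, 7), shift = 0.5)
  res <- edgewise_paired_t(mats$pre, mats$post)
  expect_equal(max(abs(res$t)), abs(res$t[2, 7]))
  expect_gt(res$t[2, 7], 0)
})

test_that("suprathreshold components are found by BFS with edge-count sizes", {
  n <- 10
  pm <- matrix(1, n, n)
  tm <- matrix(0, n, n)
  set_edge <- function(i, j) {
    pm[i, j] <<- pm[j, i] <<- 1e-5
    tm[i, j] <<- tm[j, i] <<- 5
  }
  # two disjoint triangles
  set_edge(1, 2); set_edge(2, 3); set_edge(1, 3)
  set_edge(5, 6); set_edge(6, 7); set_edge(5, 7)
  comps <- suprathreshold_components(pm, tm, 0.001)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, `[[`, integer(1), "size"), c(3L, 3L))
  expect_identical(comps[[1]]$direction, "increased")

  # a single suprathreshold edge is a 2-node component of size 1
  pm2 <- matrix(1, 4, 4)
  tm2 <- matrix(0, 4, 4)
  pm2[1, 4] <- pm2[4, 1] <- 1e-4
  tm2[1, 4] <- tm2[4, 1] <- -6
  comps <- suprathreshold_components(pm2, tm2, 0.001)
  expect_length(comps, 1L)
  expect_identical(comps[[1]]$size, 1L)
  expect_identical(comps[[1]]$node_idx, c(1L, 4L))
  expect_identical(comps[[1]]$direction, "decreased")

  # nothing suprathreshold: empty list is valid
  expect_length(suprathreshold_components(matrix(1, 3, 3),
                                          matrix(0, 3, 3), 0.001), 0L)
})

test_that("a cyclic 19-edge chain through 14 nodes is one component", {
  n <- 20
  pm <- matrix(1, n, n)
  tm <- matrix(0, n, n)
  edges <- rbind(cbind(1:13, 2:14),          # 13-edge path through 14 nodes
                 c(1, 3), c(2, 4), c(5, 7),  # chords create cycles
                 c(6, 8), c(9, 11), c(10, 12))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    pm[i, j] <- pm[j, i] <- 1e-5
    tm[i, j] <- tm[j, i] <- 4
  }
  comps <- suprathreshold_components(pm, tm, 0.001)
  expect_length(comps, 1L)
  expect_identical(comps[[1]]$size, 19L)
  expect_length(comps[[1]]$node_idx, 14L)
})

test_that("BFS component labels agree with union-find on random masks", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    pairs_all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- pairs_all[runif(nrow(pairs_all)) < 0.15, , drop = FALSE]
    comps <- conntop:::bfs_components(pairs)
    labels <- uf_components(pairs, n)
    # same partition of touched nodes
    got <- lapply(comps, `[[`, "nodes")
    touched <- sort(unique(as.vector(pairs)))
    want <- unname(split(touched, labels[touched]))
    expect_setequal(lapply(got, sort), lapply(want, sort))
    # edges partition exactly
    expect_identical(sum(vapply(comps, function(cp) length(cp$edge_idx),
                                integer(1))), nrow(pairs))
  }
})

test_that("NBS detects a planted shift and is reproducible and order-invariant", {
  set.seed(53)
  mats <- make_paired_mats(9, 12, shift_edge = c(3, 8), shift = 0.6,
                           sd = 0.05)
  a <- nbs_fwe(mats$pre, mats$post, n_perm = 300, seed = 5)
  b <- nbs_fwe(mats$pre, mats$post, n_perm = 300, seed = 5)
  expect_identical(a$null_max_sizes, b$null_max_sizes)
  expect_gte(length(a$components), 1L)
  top <- a$components[[1]]
  expect_true(any(top$edge_idx_matrix[, 1] == 3 &
                    top$edge_idx_matrix[, 2] == 8))
  expect_identical(top$direction, "increased")

  # subject reordering changes nothing observable
  perm <- sample(9)
  c_res <- nbs_fwe(mats$pre[perm], mats$post[perm], n_perm = 300, seed = 5)
  expect_equal(c_res$t_matrix, a$t_matrix)
  expect_equal(vapply(c_res$components, `[[`, integer(1), "size"),
               vapply(a$components, `[[`, integer(1), "size"))
})

test_that("component FWE p-values are monotone nonincreasing in size", {
  set.seed(54)
  mats <- make_paired_mats(8, 14, sd = 0.3)
  res <- nbs_fwe(mats$pre, mats$post, primary_alpha = 0.05, n_perm = 200,
                 seed = 2)
  sizes <- vapply(res$components, `[[`, integer(1), "size")
  ps <- vapply(res$components, `[[`, numeric(1), "fwe_p")
  if (length(sizes) >= 2) {
    expect_false(is.unsorted(ps))          # sizes sorted descending
    expect_false(is.unsorted(rev(sizes)))
  }
  # invariant holds by construction of the add-one estimator
  for (cp in res$components) {
    expect_equal(cp$fwe_p,
                 (1 + sum(res$null_max_sizes >= cp$size)) / (1 + 200))
  }
})

test_that("shrinking the primary alpha shrinks the suprathreshold set", {
  set.seed(55)
  mats <- make_paired_mats(8, 12, sd = 0.2)
  res <- edgewise_paired_t(mats$pre, mats$post)
  prev <- NULL
  for (alpha in c(0.2, 0.05, 0.01, 0.001)) {
    comps <- suprathreshold_components(res$p, res$t, alpha)
    edges <- do.call(rbind, lapply(comps, `[[`, "edge_idx_matrix"))
    keys <- if (is.null(edges)) character(0) else
      paste(edges[, 1], edges[, 2])
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("exhaustive NBS enumeration engages for small cohorts", {
  set.seed(56)
  mats <- make_paired_mats(5, 8, shift_edge = c(1, 5), shift = 0.6,
                           sd = 0.05)
  res <- nbs_fwe(mats$pre, mats$post, n_perm = 200, seed = 1)
  expect_identical(res$method, "exhaustive")
  expect_identical(res$n_perm, 32L)
  expect_length(res$null_max_sizes, 32L)
})
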