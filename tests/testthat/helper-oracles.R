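# Independent brute-force oracles for the topology and inference suites.
# Deliberately naive: enumeration and normal equations, no shared code with
# the package implementations.

# Shortest-path distances by depth-first enumeration of simple paths
# (pruned at the incumbent best length); edge length = 1/weight.
oracle_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      best <- Inf
      dfs <- function(v, visited, acc) {
        if (acc >= best) return(invisible())
        if (v == t) {
          best <<- acc
          return(invisible())
        }
        for (u in which(w[v, ] > 0)) {
          if (!visited[u]) dfs(u, `[<-`(visited, u, TRUE), acc + len[v, u])
        }
      }
      dfs(s, `[<-`(logical(n), s, TRUE), 0)
      d[s, t] <- d[t, s] <- best
    }
  }
  d
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  inv <- 1 / oracle_distances(w)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nbr <- which(w[i, ] > 0)
    if (length(nbr) < 2) return(0)
    oracle_global_efficiency(w[nbr, nbr, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Onnela weighted clustering by explicit triple loops.
oracle_clustering <- function(w) {
  n <- nrow(w)
  if (max(w) == 0) return(list(nodal = rep(0, n), mean = 0))
  wh <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
      }
    }
    nodal[i] <- acc / (k[i] * (k[i] - 1))
  }
  list(nodal = nodal, mean = mean(nodal))
}

# Betweenness by enumerating every shortest path with even splitting.
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  d <- oracle_distances(w)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(d[s, t])) next
      paths <- list()
      dfs <- function(v, visited, acc, path) {
        if (acc > d[s, t] + tol) return(invisible())
        if (v == t) {
          if (abs(acc - d[s, t]) <= tol) paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        for (u in which(w[v, ] > 0)) {
          if (!visited[u]) {
            dfs(u, `[<-`(visited, u, TRUE), acc + len[v, u], c(path, u))
          }
        }
      }
      dfs(s, `[<-`(logical(n), s, TRUE), 0, s)
      np <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / np
      }
    }
  }
  btw
}

# Trapezoid AUC as an explicit sum.
oracle_auc <- function(y, x) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) {
    acc <- acc + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  acc
}

# Union-find component labels for an edge list over n nodes.
uf_components <- function(pairs, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_len(nrow(pairs))) {
    a <- find(pairs[e, 1])
    b <- find(pairs[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# Partial correlation by explicit normal equations.
oracle_partial_cor <- function(x, y, covs) {
  X <- cbind(1, as.matrix(covs))
  beta_x <- solve(t(X) %*% X, t(X) %*% x)
  beta_y <- solve(t(X) %*% X, t(X) %*% y)
  rx <- x - X %*% beta_x
  ry <- y - X %*% beta_y
  as.numeric(stats::cor(rx, ry))
}

# Random connected-ish weighted graph: symmetric, weights in (0.1, 1).
random_weighted_graph <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on_edges <- ut[stats::runif(length(ut)) < p_edge]
  w[on_edges] <- stats::runif(length(on_edges), 0.1, 1)
  w + t(w)
}

# Exact signed-rank two-tailed p by enumerating all sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}
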