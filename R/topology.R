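# Weighted topological metrics on thresholded connectivity networks.
#
# Convention fixed across the package: the length of an edge for shortest-path
# purposes is the reciprocal of its weight (strong correlation = short
# distance), the standard mapping for correlation-weighted connectomes.

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted shortest-path length matrix
#'
#' Dijkstra distances with edge length `1/weight`; unreachable pairs are
#' `Inf`, the diagonal is 0.
#'
#' @param net A `thresholded_network` or nonnegative symmetric adjacency
#'   matrix.
#' @return N x N distance matrix.
#' @export
shortest_path_lengths <- function(net) {
  adj <- as_adjacency(net)
  g <- as_igraph(adj)
  w <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(w)) 1 / w else NULL,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(adj)
  d
}

#' Global (network) efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs,
#' `E_net = (1/(N(N-1))) * sum_{i != j} 1/d_ij`, with `1/Inf := 0`. Indexes
#' functional integration; equals 1 for a complete unit-weight graph and 0
#' for an edgeless one.
#'
#' @inheritParams shortest_path_lengths
#' @return Scalar efficiency in `[0, Inf)`.
#' @export
global_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2L) stop("efficiency needs at least 2 nodes", call. = FALSE)
  d <- shortest_path_lengths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Per-node mean inverse distance to every other node,
#' `(1/(N-1)) * sum_{j != i} 1/d_ij`.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector of length N.
#' @export
nodal_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2L) stop("efficiency needs at least 2 nodes", call. = FALSE)
  inv <- 1 / shortest_path_lengths(adj)
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Characteristic path length
#'
#' Default is the harmonic-mean form
#' `L_p = N(N-1) / sum_{i != j} 1/d_ij`, which stays finite when some node
#' pairs are disconnected (infinite distances contribute 0 to the sum) and
#' satisfies `L_p = 1/E_net` exactly. The arithmetic mean over connected
#' pairs is available via `method = "mean"`.
#'
#' @inheritParams shortest_path_lengths
#' @param method `"harmonic"` (default) or `"mean"`.
#' @return Scalar path length; `Inf` with a warning for an edgeless graph.
#' @export
characteristic_path_length <- function(net,
                                       method = c("harmonic", "mean")) {
  method <- match.arg(method)
  adj <- as_adjacency(net)
  n <- nrow(adj)
  d <- shortest_path_lengths(adj)
  off <- d[upper.tri(d) | lower.tri(d)]
  if (method == "harmonic") {
    s <- sum(1 / off)
    if (s == 0) {
      warning("fully disconnected network: characteristic path length is Inf")
      return(Inf)
    }
    n * (n - 1) / s
  } else {
    fin <- off[is.finite(off)]
    if (length(fin) == 0L) {
      warning("fully disconnected network: characteristic path length is Inf")
      return(Inf)
    }
    mean(fin)
  }
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Weights are normalized by the network maximum, and each node's coefficient
#' is the geometric mean of triangle weights over its neighbor pairs:
#' `C_i = (1/(k_i(k_i-1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)`, with
#' `C_i = 0` for nodes of binary degree below 2. `C_p` is the mean over
#' nodes; it indexes functional segregation.
#'
#' @inheritParams shortest_path_lengths
#' @return List with `nodal` (length-N vector) and `mean` (`C_p`).
#' @export
clustering_coefficient <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  mx <- max(adj)
  if (mx == 0) return(list(nodal = rep(0, n), mean = 0))
  wh <- (adj / mx)^(1 / 3)
  k <- rowSums(adj > 0)
  num <- diag(wh %*% wh %*% wh)
  nodal <- ifelse(k >= 2, num / (k * pmax(k - 1, 1)), 0)
  list(nodal = as.numeric(nodal), mean = mean(nodal))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (original weights retained); nodes with fewer than two
#' neighbors contribute 0.
#'
#' @inheritParams shortest_path_lengths
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nbr <- which(adj[i, ] > 0)
    if (length(nbr) < 2L) return(0)
    global_efficiency(adj[nbr, nbr, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness on edge lengths `1/weight`, with
#' even splitting of credit across equal-length shortest paths.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector of length N.
#' @export
betweenness_centrality <- function(net) {
  adj <- as_adjacency(net)
  g <- as_igraph(adj)
  w <- igraph::E(g)$weight
  b <- igraph::betweenness(g, weights = if (length(w)) 1 / w else NULL,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), rownames(adj))
}

#' Nodal degree (weighted strength)
#'
#' Default is the weighted strength, the sum of a node's retained edge
#' weights; `weighted = FALSE` gives the binary degree (edge count).
#'
#' @inheritParams shortest_path_lengths
#' @param weighted Use edge weights (default) or binary counts.
#' @return Numeric vector of length N.
#' @export
node_degree <- function(net, weighted = TRUE) {
  adj <- as_adjacency(net)
  if (weighted) rowSums(adj) else rowSums(adj > 0)
}

#' Null-model clustering and path length from degree-preserving surrogates
#'
#' Generates `n_null` surrogate networks by Maslov-Sneppen double-edge swaps
#' on the binary topology (preserving every node's binary degree) and
#' re-assigning the observed weight multiset to the rewired edges in random
#' order, then averages `C_p` and `L_p` over the surrogates. These means
#' normalize the observed metrics into `gamma`, `lambda` and small-worldness.
#' When the topology admits no rewiring (complete graphs, or fewer than two
#' edges) the null degenerates to a weight shuffle on the fixed topology and
#' a warning is issued.
#'
#' @inheritParams shortest_path_lengths
#' @param n_null Number of surrogate networks (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param swaps_per_edge Double-edge-swap attempts per edge per surrogate.
#' @param return_surrogates Also return the surrogate adjacency matrices
#'   (for inspection; off by default).
#' @return List with `C_p_rand` and `L_p_rand` (surrogate means), plus
#'   `surrogates` when requested.
#' @export
random_null_metrics <- function(net, n_null = 100, seed = NULL,
                                swaps_per_edge = 10,
                                return_surrogates = FALSE) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n_null < 1L) stop("n_null must be >= 1", call. = FALSE)
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(ut)
  weights <- adj[upper.tri(adj)][adj[upper.tri(adj)] > 0]
  complete <- m == n * (n - 1) / 2
  rewirable <- m >= 2L && !complete
  if (!rewirable) {
    warning("topology admits no degree-preserving rewiring; ",
            "using weight-shuffle-only null")
  }
  g <- as_igraph(adj)
  with_seed(seed, {
    cp <- lp <- numeric(n_null)
    surrs <- if (return_surrogates) vector("list", n_null) else NULL
    for (b in seq_len(n_null)) {
      if (rewirable) {
        g2 <- igraph::rewire(g, igraph::keeping_degseq(
          niter = swaps_per_edge * m))
        el <- igraph::as_edgelist(g2, names = FALSE)
      } else {
        el <- ut
      }
      surr <- matrix(0, n, n)
      surr[el] <- sample(weights)
      surr <- surr + t(surr)
      if (return_surrogates) surrs[[b]] <- surr
      cp[b] <- clustering_coefficient(surr)$mean
      lp[b] <- characteristic_path_length(surr)
    }
    out <- list(C_p_rand = mean(cp), L_p_rand = mean(lp))
    if (return_surrogates) out$surrogates <- surrs
    out
  })
}

#' Small-worldness
#'
#' `sigma = gamma / lambda`, the ratio of normalized clustering to normalized
#' path length; values above 1 indicate small-world organization.
#'
#' @param gamma Normalized clustering coefficient `C_p / C_p_rand`.
#' @param lambda Normalized characteristic path length `L_p / L_p_rand`.
#' @return Scalar sigma.
#' @export
small_world <- function(gamma, lambda) {
  if (any(lambda == 0)) stop("lambda must be nonzero", call. = FALSE)
  gamma / lambda
}

#' Area under a metric curve over the sparsity grid
#'
#' Threshold-insensitive summary of a topological metric: the integral of the
#' metric across the sparsity grid, by the trapezoidal rule (default) or a
#' left-endpoint rectangle rule.
#'
#' @param curve Numeric vector of metric values, one per grid point; must be
#'   finite.
#' @param grid Sparsity grid (ordered, length >= 2, same length as `curve`).
#' @param rule `"trapezoid"` (default) or `"rectangle"`.
#' @return Scalar AUC; a constant curve `c` yields `c * (upper - lower)`.
#' @export
auc_over_grid <- function(curve, grid, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (length(grid) < 2L) stop("grid needs at least 2 points", call. = FALSE)
  if (length(curve) != length(grid)) {
    stop("curve and grid lengths differ", call. = FALSE)
  }
  if (any(!is.finite(curve))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  h <- diff(grid)
  if (rule == "trapezoid") {
    sum(h * (curve[-length(curve)] + curve[-1L]) / 2)
  } else {
    sum(h * curve[-length(curve)])
  }
}

#' Full topological metric pipeline for one connectivity matrix
#'
#' Thresholds the (sub)network at every sparsity value of the grid, computes
#' the seven network metrics (`E_net`, `E_loc`, `L_p`, `C_p`, `gamma`,
#' `lambda`, `sigma`) and the three nodal metrics (`degree`, `efficiency`,
#' `betweenness`) at each point, and aggregates every curve to its AUC.
#'
#' @param cm Connectivity matrix. If `atlas` and `label` are given it is the
#'   whole-atlas matrix and the subnetwork is extracted first; otherwise it
#'   is used as-is.
#' @param atlas Optional `conntop_atlas`.
#' @param label Optional subnetwork label.
#' @param grid Sparsity grid; defaults to [sparsity_grid()] for the
#'   (sub)network size.
#' @param n_null Surrogates per grid point for `gamma`/`lambda`/`sigma`;
#'   set 0 to skip the normalized metrics (they become `NA`).
#' @param seed Optional seed for the null surrogates.
#' @param lp_method Path-length convention, see
#'   [characteristic_path_length()].
#' @param auc_rule Integration rule, see [auc_over_grid()].
#' @return A `metric_curves` object: list with `grid`, `network` (data frame,
#'   grid x 7 metrics), `nodal` (list of three grid x N matrices), and `auc`
#'   (list with `network`, a named vector, and `nodal`, a 3 x N matrix).
#'   Curves containing non-finite values get `NA` AUC with a warning.
#' @export
metric_pipeline <- function(cm, atlas = NULL, label = NULL, grid = NULL,
                            n_null = 100, seed = NULL,
                            lp_method = c("harmonic", "mean"),
                            auc_rule = c("trapezoid", "rectangle")) {
  lp_method <- match.arg(lp_method)
  auc_rule <- match.arg(auc_rule)
  if (!is.null(label)) {
    if (is.null(atlas)) stop("label requires an atlas", call. = FALSE)
    cm <- extract_subnetwork(cm, atlas, label)
  }
  n <- nrow(cm)
  if (is.null(grid)) grid <- sparsity_grid(n_nodes = n)
  ng <- length(grid)
  net_names <- c("E_net", "E_loc", "L_p", "C_p", "gamma", "lambda", "sigma")
  network <- matrix(NA_real_, ng, length(net_names),
                    dimnames = list(NULL, net_names))
  nodal <- list(degree = matrix(NA_real_, ng, n),
                efficiency = matrix(NA_real_, ng, n),
                betweenness = matrix(NA_real_, ng, n))
  for (k in seq_len(ng)) {
    net <- threshold_network(cm, grid[k])
    cc <- clustering_coefficient(net)
    e_net <- global_efficiency(net)
    l_p <- characteristic_path_length(net, method = lp_method)
    network[k, "E_net"] <- e_net
    network[k, "E_loc"] <- local_efficiency(net)
    network[k, "L_p"] <- l_p
    network[k, "C_p"] <- cc$mean
    if (n_null > 0) {
      nul <- random_null_metrics(net, n_null = n_null,
                                 seed = if (is.null(seed)) NULL else seed + k)
      gamma <- cc$mean / nul$C_p_rand
      lambda <- l_p / nul$L_p_rand
      network[k, "gamma"] <- gamma
      network[k, "lambda"] <- lambda
      network[k, "sigma"] <- small_world(gamma, lambda)
    }
    nodal$degree[k, ] <- node_degree(net)
    nodal$efficiency[k, ] <- nodal_efficiency(net)
    nodal$betweenness[k, ] <- betweenness_centrality(net)
  }
  safe_auc <- function(y) {
    if (any(!is.finite(y))) {
      warning("non-finite metric values on the grid; AUC set to NA")
      return(NA_real_)
    }
    auc_over_grid(y, grid, rule = auc_rule)
  }
  auc_network <- stats::setNames(vapply(net_names, function(mn) {
    if (all(is.na(network[, mn]))) NA_real_ else safe_auc(network[, mn])
  }, numeric(1)), net_names)
  auc_nodal <- do.call(rbind, lapply(nodal, function(mat)
    apply(mat, 2L, safe_auc)))
  colnames(auc_nodal) <- colnames(cm)
  structure(list(grid = grid, network = as.data.frame(network),
                 nodal = nodal,
                 auc = list(network = auc_network, nodal = auc_nodal)),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("topological metric curves over", length(x$grid),
      sprintf("sparsity values [%.2f, %.2f]\n", min(x$grid), max(x$grid)))
  cat("network metric AUCs:\n")
  print(round(x$auc$network, 4))
  invisible(x)
}
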