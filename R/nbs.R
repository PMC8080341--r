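# Network-based statistic (NBS) for paired designs: edgewise paired t-tests,
# suprathreshold component formation by breadth-first search, and permutation
# family-wise error control on maximal component size.

upper_tri_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Stack the upper triangles of paired connectivity matrices into a
# subjects x edges difference matrix.
paired_diff_matrix <- function(pre_nets, post_nets) {
  if (length(pre_nets) != length(post_nets)) {
    stop("pre and post subject lists differ in length", call. = FALSE)
  }
  n_sub <- length(pre_nets)
  if (n_sub < 3L) stop("need at least 3 subjects", call. = FALSE)
  n <- nrow(pre_nets[[1L]])
  ut <- upper.tri(pre_nets[[1L]])
  d <- t(vapply(seq_len(n_sub), function(s) {
    pre <- as.matrix(pre_nets[[s]])
    post <- as.matrix(post_nets[[s]])
    if (!all(dim(pre) == c(n, n)) || !all(dim(post) == c(n, n))) {
      stop("all connectivity matrices must share dimensions", call. = FALSE)
    }
    post[ut] - pre[ut]
  }, numeric(sum(ut))))
  list(d = d, n_nodes = n, pairs = upper_tri_pairs(n),
       labels = rownames(pre_nets[[1L]]))
}

# Paired t statistics for every edge from the difference matrix; zero-variance
# edges get +/-Inf (nonzero mean) or 0.
edge_t_from_diffs <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
  list(t = t, df = n - 1L)
}

#' Edgewise paired t-tests on connectivity matrices
#'
#' Paired two-tailed t-test of post vs pre correlation at every edge of the
#' (unthresholded) connectivity matrices, irrespective of direction. Edges
#' with zero difference variance are flagged with a warning: a nonzero mean
#' gives `t = +/-Inf` (always suprathreshold), a zero mean gives `t = 0`.
#'
#' @param pre_nets,post_nets Lists of N x N connectivity matrices, aligned by
#'   subject, at least 3 subjects.
#' @return List with `t` and `p` (symmetric N x N matrices, zero diagonal)
#'   and `df`.
#' @export
edgewise_paired_t <- function(pre_nets, post_nets) {
  pd <- paired_diff_matrix(pre_nets, post_nets)
  et <- edge_t_from_diffs(pd$d)
  if (any(!is.finite(et$t))) {
    warning(sum(!is.finite(et$t)),
            " edge(s) with zero-variance nonzero difference: t = +/-Inf, ",
            "treated as suprathreshold")
  }
  p_vec <- ifelse(is.finite(et$t), 2 * stats::pt(-abs(et$t), et$df), 0)
  n <- pd$n_nodes
  tm <- pm <- matrix(0, n, n, dimnames = list(pd$labels, pd$labels))
  tm[pd$pairs] <- et$t
  pm[pd$pairs] <- p_vec
  tm <- tm + t(tm)
  pm <- pm + t(pm)
  diag(pm) <- 0
  list(t = tm, p = pm, df = et$df)
}

# Connected components of an edge set by breadth-first search.
# pairs: E x 2 matrix of node indices. Returns a list of components, each
# with sorted member nodes and edge indices into `pairs`.
bfs_components <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  nodes <- sort(unique(as.vector(pairs)))
  nn <- length(nodes)
  ei <- match(pairs[, 1L], nodes)
  ej <- match(pairs[, 2L], nodes)
  inc <- vector("list", nn)
  for (e in seq_along(ei)) {
    inc[[ei[e]]] <- c(inc[[ei[e]]], e)
    inc[[ej[e]]] <- c(inc[[ej[e]]], e)
  }
  visited <- logical(nn)
  comps <- list()
  for (s in seq_len(nn)) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    members <- integer(0)
    edges <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      members <- c(members, v)
      for (e in inc[[v]]) {
        edges <- c(edges, e)
        u <- if (ei[e] == v) ej[e] else ei[e]
        if (!visited[u]) {
          visited[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1L]] <- list(nodes = nodes[sort(members)],
                                        edge_idx = sort(unique(edges)))
  }
  comps
}

max_component_size <- function(pairs) {
  comps <- bfs_components(pairs)
  if (length(comps) == 0L) return(0L)
  max(vapply(comps, function(cp) length(cp$edge_idx), integer(1)))
}

#' Connected components of suprathreshold edges
#'
#' Edges with `p < primary_alpha` form a graph whose connected components
#' (found by breadth-first search) are the candidate effects; component size
#' is the number of edges ("links"). Each component is annotated with the
#' sign of its edge t-values so components of increased connectivity are
#' identifiable.
#'
#' @param p_matrix,t_matrix Symmetric matrices from [edgewise_paired_t()].
#' @param primary_alpha Primary (uncorrected) edge threshold, default 0.001.
#' @return List of components sorted by size descending; each has `nodes`
#'   (names when available, else indices), `node_idx`, `edges` (edge x 2 of
#'   node labels), `edge_idx_matrix` (edge x 2 of node indices), `size`,
#'   `mean_t`, `direction` (`"increased"`, `"decreased"` or `"mixed"`).
#'   Empty list when nothing survives the threshold.
#' @export
suprathreshold_components <- function(p_matrix, t_matrix,
                                      primary_alpha = 0.001) {
  n <- nrow(p_matrix)
  pairs_all <- upper_tri_pairs(n)
  supra <- p_matrix[pairs_all] < primary_alpha
  pairs <- pairs_all[supra, , drop = FALSE]
  comps <- bfs_components(pairs)
  labels <- rownames(p_matrix)
  out <- lapply(comps, function(cp) {
    ep <- pairs[cp$edge_idx, , drop = FALSE]
    tvals <- t_matrix[ep]
    dir <- if (all(tvals > 0)) "increased"
           else if (all(tvals < 0)) "decreased" else "mixed"
    lab <- function(i) if (is.null(labels)) i else labels[i]
    list(nodes = lab(cp$nodes),
         node_idx = cp$nodes,
         edges = cbind(lab(ep[, 1L]), lab(ep[, 2L])),
         edge_idx_matrix = ep,
         size = nrow(ep),
         mean_t = mean(tvals),
         direction = dir)
  })
  out[order(-vapply(out, `[[`, integer(1), "size"))]
}

#' Network-based statistic with permutation family-wise error control
#'
#' Full paired NBS: edgewise paired t-tests on unthresholded connectivity
#' matrices, suprathreshold component formation at `primary_alpha`, and a
#' permutation null of maximal component size built by randomly exchanging
#' each subject's pre/post labels (equivalently, sign-flipping paired
#' differences). A component is family-wise significant when its size ranks
#' in the top `100 * fwe_alpha`% of the permuted maxima. All `2^n` label
#' exchanges are enumerated when that is no larger than `n_perm`.
#'
#' @inheritParams edgewise_paired_t
#' @param primary_alpha Primary edge threshold (default 0.001, two-tailed).
#' @param n_perm Number of permutations (default 10000, >= 100).
#' @param seed Optional integer seed (RNG state preserved).
#' @param fwe_alpha Family-wise significance level (default 0.05).
#' @return An `nbs_result`: `t_matrix`, `p_matrix`, `components` (as in
#'   [suprathreshold_components()], each with `fwe_p` and `significant`),
#'   `null_max_sizes`, `n_suprathreshold`, `primary_alpha`, `n_perm`,
#'   `method`, `seed`.
#' @export
nbs_fwe <- function(pre_nets, post_nets, primary_alpha = 0.001,
                    n_perm = 10000, seed = NULL, fwe_alpha = 0.05) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  pd <- paired_diff_matrix(pre_nets, post_nets)
  n_sub <- nrow(pd$d)
  obs <- edgewise_paired_t(pre_nets, post_nets)
  comps <- suprathreshold_components(obs$p, obs$t, primary_alpha)
  tcrit <- stats::qt(1 - primary_alpha / 2, df = n_sub - 1L)

  exhaustive <- 2^n_sub <= n_perm
  signs <- if (exhaustive) {
    sign_matrix(n_sub)
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                           n_perm, n_sub))
  }
  n_eff <- nrow(signs)
  ss <- colSums(pd$d^2)
  null_max <- integer(n_eff)
  chunk <- max(1L, min(n_eff, as.integer(2^22 / max(1L, ncol(pd$d)))))
  for (start in seq.int(1L, n_eff, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_eff)
    m <- signs[idx, , drop = FALSE] %*% pd$d / n_sub
    v <- sweep(-n_sub * m^2, 2L, ss, "+") / (n_sub - 1L)
    v[v < 0] <- 0
    tmat <- abs(m) / sqrt(v / n_sub)
    tmat[v == 0] <- ifelse(m[v == 0] == 0, 0, Inf)
    supra <- tmat > tcrit
    any_edge <- rowSums(supra) > 0L
    for (r in which(any_edge)) {
      null_max[idx[r]] <- max_component_size(
        pd$pairs[supra[r, ], , drop = FALSE])
    }
  }

  comps <- lapply(comps, function(cp) {
    cp$fwe_p <- if (exhaustive) {
      mean(null_max >= cp$size)
    } else {
      (1 + sum(null_max >= cp$size)) / (1 + n_perm)
    }
    cp$significant <- cp$fwe_p < fwe_alpha
    cp
  })
  structure(list(t_matrix = obs$t, p_matrix = obs$p, components = comps,
                 null_max_sizes = null_max,
                 n_suprathreshold = sum(obs$p[upper.tri(obs$p)] <
                                          primary_alpha),
                 primary_alpha = primary_alpha, n_perm = n_eff,
                 method = if (exhaustive) "exhaustive" else "monte-carlo",
                 seed = seed),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("network-based statistic:", x$n_suprathreshold,
      "suprathreshold edge(s) at p <", x$primary_alpha, "\n")
  if (length(x$components) == 0L) {
    cat("no connected components\n")
  } else {
    for (cp in x$components) {
      cat(sprintf(" component: %d node(s), %d edge(s), %s, FWE p = %.4g%s\n",
                  length(cp$nodes), cp$size, cp$direction, cp$fwe_p,
                  if (cp$significant) " *" else ""))
    }
  }
  invisible(x)
}
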