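#' Pearson correlation connectivity matrix
#'
#' Functional edges are Pearson correlations between the mean time series of
#' every pair of nodes. The diagonal is stored as 0 by convention (self
#' connectivity is undefined for this analysis).
#'
#' @param ts Numeric matrix, time points x ROIs, `T >= 3`.
#' @return Symmetric N x N matrix of pairwise Pearson r with zero diagonal;
#'   ROI names carried over as dimnames when present.
#' @export
compute_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else as.character(bad)
    stop("constant time series for ROI(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  cm <- stats::cor(ts)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 0
  cm
}

#' Extract a subnetwork connectivity matrix
#'
#' Takes the principal submatrix over the ROIs carrying the requested
#' subnetwork label, preserving atlas order, so the subnetwork can be analyzed
#' as a smaller but structurally identical graph.
#'
#' @param cm N x N connectivity matrix over the full atlas.
#' @param atlas A `conntop_atlas` object with `nrow(atlas) == nrow(cm)`.
#' @param label Subnetwork label (e.g. `"DMN"`, `"FPN"`, `"CON"`).
#' @return Principal submatrix with `roi_name` dimnames.
#' @export
extract_subnetwork <- function(cm, atlas, label) {
  if (nrow(cm) != nrow(atlas)) {
    stop("connectivity matrix size (", nrow(cm),
         ") does not match atlas (", nrow(atlas), ")", call. = FALSE)
  }
  idx <- atlas_rois(atlas, label)
  sub <- cm[idx, idx, drop = FALSE]
  dimnames(sub) <- list(atlas$roi_name[idx], atlas$roi_name[idx])
  sub
}

# Edge count at sparsity s over E_max possible edges. The 1e-9 nudge keeps
# exact lattice products (e.g. 0.30 * 210 = 63) from flooring one short under
# binary floating point.
edge_count_at <- function(sparsity, e_max) {
  as.integer(floor(sparsity * e_max + 1e-9))
}

#' Lower sparsity bound from the minimum-edge rule
#'
#' The sparsity grid's lower bound depends on network scale: it is the
#' smallest value on the step lattice whose retained edge count
#' `floor(s * N(N-1)/2)` is strictly larger than `(N/2) * ln(N)`, which keeps
#' enough edges for estimable topological metrics. For the subnetwork sizes
#' 34, 21 and 32 this yields 0.11, 0.16 and 0.12 on a 0.01 grid.
#'
#' @param n_nodes Number of nodes, at least 3.
#' @param step Grid increment (default 0.01).
#' @param upper Largest admissible sparsity (default 0.4).
#' @return The lower bound, a multiple of `step`.
#' @export
sparsity_lower_bound <- function(n_nodes, step = 0.01, upper = 0.4) {
  if (n_nodes < 3L) stop("need at least 3 nodes", call. = FALSE)
  e_max <- n_nodes * (n_nodes - 1) / 2
  min_edges <- n_nodes / 2 * log(n_nodes)
  for (k in seq_len(as.integer(floor(upper / step + 1e-9)))) {
    s <- k * step
    if (edge_count_at(s, e_max) > min_edges) return(round(s, 10L))
  }
  stop("no sparsity value up to ", upper, " retains more than ",
       format(min_edges), " edges for N = ", n_nodes, call. = FALSE)
}

#' Sparsity threshold grid
#'
#' Ordered lattice of sparsity values from the scale-dependent lower bound
#' (see [sparsity_lower_bound()]) to the empirical upper bound 0.4, inclusive.
#'
#' @param n_nodes Number of nodes (used to derive `lower` when not given).
#' @param lower Optional explicit lower bound (multiple of `step`).
#' @param upper Upper bound (default 0.4).
#' @param step Grid increment (default 0.01).
#' @return Numeric vector of grid values.
#' @export
sparsity_grid <- function(n_nodes = NULL, lower = NULL, upper = 0.4,
                          step = 0.01) {
  if (is.null(lower)) {
    if (is.null(n_nodes)) stop("give either n_nodes or lower", call. = FALSE)
    lower <- sparsity_lower_bound(n_nodes, step = step, upper = upper)
  }
  k_lo <- as.integer(round(lower / step))
  k_hi <- as.integer(floor(upper / step + 1e-9))
  if (k_lo > k_hi) stop("lower exceeds upper", call. = FALSE)
  round(seq.int(k_lo, k_hi) * step, 10L)
}

#' Threshold a connectivity matrix at a sparsity level
#'
#' Keeps the `K = floor(s * N(N-1)/2)` edges with the largest signed
#' correlation, carrying the correlation as the edge weight; all other entries
#' become 0. Ties at the cutoff are broken deterministically by (weight
#' descending, row ascending, column ascending) so results are reproducible
#' bit for bit. Any retained negative weight is clamped to 0 with a warning:
#' the weighted metrics assume nonnegative weights, and negative correlations
#' can only reach the retained set at high sparsity.
#'
#' @param cm Symmetric connectivity matrix with zero diagonal.
#' @param sparsity Sparsity in (0, 1].
#' @return A `thresholded_network`: list with `adjacency` (N x N symmetric
#'   nonnegative weights), `sparsity`, and `n_edges` (retained count `K`,
#'   before any negative-weight clamping).
#' @export
threshold_network <- function(cm, sparsity) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]",
                                          call. = FALSE)
  e_max <- n * (n - 1) / 2
  k <- edge_count_at(sparsity, e_max)
  if (k == 0L) stop("sparsity ", sparsity, " retains no edges for N = ", n,
                    call. = FALSE)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[ut]
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(k)]
  adj <- matrix(0, n, n, dimnames = dimnames(cm))
  wk <- w[keep]
  if (any(wk < 0)) {
    warning(sum(wk < 0), " retained edge(s) had negative correlation; ",
            "clamped to 0 for metric computation")
    wk[wk < 0] <- 0
  }
  adj[ut[keep, , drop = FALSE]] <- wk
  adj <- adj + t(adj)
  structure(list(adjacency = adj, sparsity = sparsity, n_edges = k),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat("thresholded network:", nrow(x$adjacency), "nodes,", x$n_edges,
      "edges at sparsity", x$sparsity, "\n")
  invisible(x)
}

# Accept either a thresholded_network or a bare adjacency matrix.
as_adjacency <- function(net) {
  if (inherits(net, "thresholded_network")) net$adjacency else as.matrix(net)
}
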