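# Non-parametric inference for paired (pre/post) designs.

check_paired <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  if (length(pre) < 2L) stop("need at least 2 paired observations",
                             call. = FALSE)
  if (anyNA(pre) || anyNA(post)) stop("paired values contain NA",
                                      call. = FALSE)
  invisible(NULL)
}

# All 2^n sign vectors as a (+/-1) matrix, rows = assignments.
sign_matrix <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Paired sign-flip permutation test
#'
#' Tests the mean paired difference `mean(post - pre)` against the null of
#' exchangeable pre/post labels within subject: the null distribution is
#' built by randomly flipping the sign of each subject's difference. When the
#' full set of `2^n` sign assignments is no larger than `n_perm` it is
#' enumerated exhaustively and the p-value is the exact proportion
#' `#{|null| >= |observed|} / 2^n`; otherwise `n_perm` random flips are drawn
#' and the add-one estimate `(1 + #{|null| >= |observed|}) / (1 + n_perm)`
#' is used so that p is never 0.
#'
#' @param pre,post Aligned numeric vectors of per-subject values (e.g. metric
#'   AUCs at baseline and endpoint).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed (RNG state preserved).
#' @return A `perm_test` list: `observed` (mean difference), `null`
#'   (permuted statistics), `p` (two-tailed), `n_perm`, `method`
#'   (`"exhaustive"` or `"monte-carlo"`), `seed`.
#' @export
paired_permutation_test <- function(pre, post, n_perm = 10000, seed = NULL) {
  check_paired(pre, post)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  d <- as.numeric(post) - as.numeric(pre)
  n <- length(d)
  observed <- mean(d)
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(observed = 0, null = numeric(0), p = 1,
                          n_perm = n_perm, method = "degenerate",
                          seed = seed), class = "perm_test"))
  }
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- sign_matrix(n)
    null <- as.numeric(signs %*% d) / n
    p <- mean(abs(null) >= abs(observed) - 1e-12)
    method <- "exhaustive"
  } else {
    null <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      n_perm, n)
      as.numeric(signs %*% d) / n
    })
    p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (1 + n_perm)
    method <- "monte-carlo"
  }
  structure(list(observed = observed, null = null, p = p, n_perm = n_perm,
                 method = method, seed = seed), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("paired permutation test (%s): observed mean diff = %.6g, p = %.4g\n",
              x$method, x$observed, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure for families of nodal-metric p-values; rejection at
#' level `q` is equivalent to `p_adjusted <= q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical mask) and `p_adjusted` (monotone BH
#'   adjusted p-values).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) {
    return(list(reject = logical(0), p_adjusted = numeric(0)))
  }
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}

#' Paired Wilcoxon signed-rank test
#'
#' Pre/post comparison for clinical scales. Zero differences are dropped; the
#' exact signed-rank distribution is used for up to 25 non-zero differences
#' without ties, and the tie-corrected normal approximation (no continuity
#' correction) otherwise.
#'
#' @param pre,post Aligned numeric vectors.
#' @return List with `statistic` (V, sum of positive ranks), `p` (two-tailed),
#'   `n` (non-zero differences used), `exact`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  check_paired(pre, post)
  d <- as.numeric(post) - as.numeric(pre)
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n = 0L, exact = FALSE))
  }
  if (length(nz) < 2L) stop("need at least 2 non-zero differences",
                            call. = FALSE)
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= 25L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value,
       n = length(nz), exact = exact)
}

#' Partial correlation with nuisance covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' regression on the covariates plus an intercept (the standard way to relate
#' topological change to clinical change while controlling age and sex).
#' Constant covariate columns are dropped (they are absorbed by the
#' intercept). The p-value is two-tailed from the t distribution with
#' `n - 2 - k` degrees of freedom, `k` the number of retained covariates.
#'
#' @param x,y Numeric vectors (e.g. per-subject changes).
#' @param covariates Optional numeric matrix/data frame of nuisance variables
#'   (one row per subject); `NULL` reduces to the plain Pearson correlation.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates)) {
    cmat <- matrix(numeric(0), n, 0)
  } else {
    cmat <- as.matrix(as.data.frame(covariates))
    storage.mode(cmat) <- "double"
    keep <- apply(cmat, 2L, function(col) stats::sd(col) > 0)
    cmat <- cmat[, keep, drop = FALSE]
  }
  k <- ncol(cmat)
  if (n <= k + 2L) {
    stop("need more observations than covariates plus two", call. = FALSE)
  }
  design <- cbind(Intercept = 1, cmat)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("covariates are collinear", call. = FALSE)
  }
  rx <- stats::resid(stats::lm.fit(design, x))
  ry <- stats::resid(stats::lm.fit(design, y))
  tol_x <- 1e-10 * max(stats::sd(x), 1)
  tol_y <- 1e-10 * max(stats::sd(y), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y) {
    stop("zero residual variance: a variable is collinear with the covariates",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, df = df, n = n)
}

#' Bonferroni rejection mask
#'
#' Rejects where `p < alpha / n_tests`, the family-wise control used for the
#' brain-behavior correlation family.
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Family-wise level (default 0.05).
#' @param n_tests Family size N; defaults to `length(pvals)`.
#' @return Logical rejection mask.
#' @export
bonferroni <- function(pvals, alpha = 0.05, n_tests = length(pvals)) {
  if (n_tests < 1L) stop("n_tests must be >= 1", call. = FALSE)
  pvals < alpha / n_tests
}
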