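# Synthetic pre/post fMRI-like cohorts with known covariance structure and a
# planted connectivity effect, providing ground truth for every downstream
# stage (thresholding, topology, permutation inference, NBS).

#' Specify a synthetic cohort simulation
#'
#' The generator draws, for every subject and session, a T x N Gaussian ROI
#' time-series whose stationary spatial covariance is a blockwise correlation
#' matrix (`r_within` inside each subnetwork, `r_between` elsewhere), with
#' AR(1) temporal autocorrelation. The post-session covariance differs from
#' the pre-session one only on a connected set of planted edges inside one
#' subnetwork, whose correlation is raised by `effect_size`. Per-subject
#' heterogeneity is added as a shared (pre and post) symmetric perturbation of
#' the edge correlations. The change in the ERC clinical score is coupled
#' linearly to each subject's realized mean planted-edge correlation change.
#'
#' @param atlas A `conntop_atlas`; defaults to [synthetic_atlas()] (160 ROIs,
#'   34 DMN / 21 FPN / 32 CON).
#' @param n_subjects Number of subjects (default 10, each with a pre and a
#'   post session).
#' @param n_timepoints Retained volumes per session (default 190).
#' @param r_within Within-subnetwork baseline correlation (default 0.2).
#' @param r_between Between-subnetwork correlation (default 0.05).
#' @param planted_subnetwork Label of the subnetwork carrying the effect
#'   (default `"CON"`).
#' @param planted_edges Optional E x 2 matrix of full-atlas ROI indices; must
#'   lie within `planted_subnetwork` and form a connected graph. Default: a
#'   6-edge connected set on the subnetwork's first five ROIs.
#' @param effect_size Additive correlation increment delta applied to planted
#'   edges post vs pre (default 0.25).
#' @param ar_coefficient AR(1) coefficient phi in `[0, 0.95]` (default 0.3).
#' @param subject_sd SD of the per-subject edge-correlation perturbation
#'   (default 0.05).
#' @param clinical_beta ERC points per unit of mean planted-edge correlation
#'   change (default 20, sized so the default delta maps to a ~5-point mean
#'   ERC improvement).
#' @param clinical_noise_sd SD of the ERC change noise (default
#'   `0.1 * clinical_beta`).
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it so subsets reproduce.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(atlas = synthetic_atlas(), n_subjects = 10,
                            n_timepoints = 190, r_within = 0.2,
                            r_between = 0.05, planted_subnetwork = "CON",
                            planted_edges = NULL, effect_size = 0.25,
                            ar_coefficient = 0.3, subject_sd = 0.05,
                            clinical_beta = 20,
                            clinical_noise_sd = 0.1 * clinical_beta,
                            seed = 1) {
  stopifnot(inherits(atlas, "conntop_atlas"), n_subjects >= 1,
            n_timepoints >= 3)
  if (ar_coefficient < 0 || ar_coefficient > 0.95) {
    stop("ar_coefficient must be in [0, 0.95]", call. = FALSE)
  }
  members <- atlas_rois(atlas, planted_subnetwork)
  if (is.null(planted_edges)) {
    if (length(members) < 5L) stop("planted subnetwork too small for the ",
                                   "default planted edge set", call. = FALSE)
    v <- members[1:5]
    planted_edges <- rbind(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[4]),
                           c(v[4], v[5]), c(v[1], v[3]), c(v[2], v[4]))
  }
  planted_edges <- matrix(as.integer(planted_edges), ncol = 2L)
  planted_edges <- t(apply(planted_edges, 1L, sort))
  if (!all(planted_edges %in% members)) {
    stop("planted edges must lie within subnetwork '", planted_subnetwork,
         "'", call. = FALSE)
  }
  if (length(bfs_components(planted_edges)) != 1L) {
    stop("planted edges must form a connected graph", call. = FALSE)
  }
  if (abs(r_within + effect_size) >= 1) {
    stop("effect_size pushes planted correlations outside (-1, 1)",
         call. = FALSE)
  }
  structure(list(atlas = atlas, n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 r_within = r_within, r_between = r_between,
                 planted_subnetwork = planted_subnetwork,
                 planted_edges = planted_edges, effect_size = effect_size,
                 ar_coefficient = ar_coefficient, subject_sd = subject_sd,
                 clinical_beta = clinical_beta,
                 clinical_noise_sd = clinical_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Minimal positive-definite repair: floor eigenvalues, rebuild, rescale to
# unit diagonal.
repair_pd <- function(m, floor = 1e-6) {
  eg <- eigen(m, symmetric = TRUE)
  if (min(eg$values) >= floor) return(list(mat = m, repaired = FALSE))
  vals <- pmax(eg$values, floor)
  m2 <- eg$vectors %*% (vals * t(eg$vectors))
  d <- 1 / sqrt(diag(m2))
  m2 <- m2 * tcrossprod(d)
  m2 <- (m2 + t(m2)) / 2
  dimnames(m2) <- dimnames(m)
  list(mat = m2, repaired = TRUE)
}

#' Population pre/post covariance matrices for a simulation
#'
#' Builds the blockwise baseline correlation matrix and its post-session
#' counterpart in which the planted edges are raised by `effect_size`; both
#' are repaired to positive definiteness by minimal eigenvalue clipping if
#' necessary (reported by message).
#'
#' @param spec A `simulation_spec`.
#' @return List with `pre`, `post` (N x N correlation matrices) and
#'   `repaired` (logical pair).
#' @export
build_covariances <- function(spec) {
  atlas <- spec$atlas
  n <- nrow(atlas)
  same <- outer(atlas$subnetwork, atlas$subnetwork, "==")
  pre <- ifelse(same, spec$r_within, spec$r_between)
  diag(pre) <- 1
  dimnames(pre) <- list(atlas$roi_name, atlas$roi_name)
  post <- pre
  for (e in seq_len(nrow(spec$planted_edges))) {
    i <- spec$planted_edges[e, 1L]
    j <- spec$planted_edges[e, 2L]
    post[i, j] <- post[j, i] <- post[i, j] + spec$effect_size
  }
  off <- post[upper.tri(post)]
  if (any(abs(off) >= 1)) {
    stop("effect_size pushes a correlation outside (-1, 1)", call. = FALSE)
  }
  rp_pre <- repair_pd(pre)
  rp_post <- repair_pd(post)
  if (rp_pre$repaired || rp_post$repaired) {
    message("covariance repaired to positive definite by eigenvalue clipping")
  }
  list(pre = rp_pre$mat, post = rp_post$mat,
       repaired = c(pre = rp_pre$repaired, post = rp_post$repaired))
}

# Stationary AR(1)-colored Gaussian sample: innovations with spatial
# covariance chol_s' chol_s, x_1 at full stationary variance.
ar1_colored_sample <- function(n_t, chol_sigma, phi) {
  n <- ncol(chol_sigma)
  e <- matrix(stats::rnorm(n_t * n), n_t, n) %*% chol_sigma
  if (phi == 0 || n_t == 1L) return(e)
  c_sc <- sqrt(1 - phi^2)
  x <- apply(e, 2L, function(col) {
    c(col[1L], stats::filter(c_sc * col[-1L], phi, method = "recursive",
                             init = col[1L]))
  })
  matrix(x, n_t, n)
}

subject_substream_seed <- function(master_seed, subject_id) {
  h <- sum(utf8ToInt(subject_id) * seq_along(utf8ToInt(subject_id))) %% 100003L
  (as.integer(master_seed) %% 20011L) * 100003L + h
}

#' Simulate a pre/post cohort of ROI time series and clinical scores
#'
#' Draws every subject-session time series from the specification (see
#' [simulation_spec()]), computes each subject's realized mean planted-edge
#' correlation change, and generates a long-format clinical table (CDRS_R,
#' YMRS, CGAS, ERC) whose ERC change is linearly coupled to that realized
#' change. Fully reproducible from the spec's seed; per-subject substreams
#' make any subject subset reproducible on its own.
#'
#' @param spec A `simulation_spec`.
#' @return A `conntop_cohort`: list with `atlas`, `spec`, `subjects` (per
#'   subject: `id`, `age`, `sex`, `pre`/`post` T x N matrices, `delta_r`),
#'   `clinical` (long data frame), and `truth` (planted edge list as indices
#'   and `roi_name` pairs, delta, beta, seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  covs <- build_covariances(spec)
  atlas <- spec$atlas
  n <- nrow(atlas)
  ids <- sprintf("sub%02d", seq_len(spec$n_subjects))
  demo <- with_seed(spec$seed, {
    list(age = round(stats::runif(spec$n_subjects, 13, 17), 1),
         sex = rep_len(c("F", "M"), spec$n_subjects),
         cdrs = round(stats::rnorm(spec$n_subjects, 34.0, 17.4), 1),
         d_cdrs = round(stats::rnorm(spec$n_subjects, -4.3, 8.0), 1),
         ymrs = pmax(0, round(stats::rnorm(spec$n_subjects, 5.4, 3.6), 1)),
         d_ymrs = round(stats::rnorm(spec$n_subjects, -0.3, 2.0), 1),
         cgas = round(stats::rnorm(spec$n_subjects, 69.7, 10.8), 1),
         d_cgas = round(stats::rnorm(spec$n_subjects, 8.3, 6.0), 1),
         erc = round(stats::rnorm(spec$n_subjects, 65.0, 10.9), 1))
  })
  pe <- spec$planted_edges
  subjects <- vector("list", spec$n_subjects)
  names(subjects) <- ids
  for (s in seq_len(spec$n_subjects)) {
    sub_seed <- subject_substream_seed(spec$seed, ids[s])
    subjects[[s]] <- with_seed(sub_seed, {
      # subject-level edge-correlation perturbation, shared across sessions
      pert <- matrix(0, n, n)
      pert[upper.tri(pert)] <- stats::rnorm(n * (n - 1) / 2, 0,
                                            spec$subject_sd)
      pert <- pert + t(pert)
      make_session_cov <- function(base) {
        m <- base + pert
        m[m > 0.99] <- 0.99
        m[m < -0.99] <- -0.99
        diag(m) <- 1
        repair_pd(m)$mat
      }
      sig_pre <- make_session_cov(covs$pre)
      sig_post <- make_session_cov(covs$post)
      pre_ts <- ar1_colored_sample(spec$n_timepoints, chol(sig_pre),
                                   spec$ar_coefficient)
      post_ts <- ar1_colored_sample(spec$n_timepoints, chol(sig_post),
                                    spec$ar_coefficient)
      colnames(pre_ts) <- colnames(post_ts) <- atlas$roi_name
      r_pre <- vapply(seq_len(nrow(pe)), function(e)
        stats::cor(pre_ts[, pe[e, 1L]], pre_ts[, pe[e, 2L]]), numeric(1))
      r_post <- vapply(seq_len(nrow(pe)), function(e)
        stats::cor(post_ts[, pe[e, 1L]], post_ts[, pe[e, 2L]]), numeric(1))
      d_erc <- spec$clinical_beta * mean(r_post - r_pre) +
        stats::rnorm(1, 0, spec$clinical_noise_sd)
      list(id = ids[s], age = demo$age[s], sex = demo$sex[s],
           pre = pre_ts, post = post_ts,
           delta_r = mean(r_post - r_pre), d_erc = d_erc)
    })
  }
  clinical <- do.call(rbind, lapply(seq_len(spec$n_subjects), function(s) {
    sub <- subjects[[s]]
    data.frame(
      subject = rep(sub$id, 2L), session = c("pre", "post"),
      age = rep(sub$age, 2L), sex = rep(sub$sex, 2L),
      CDRS_R = c(demo$cdrs[s], demo$cdrs[s] + demo$d_cdrs[s]),
      YMRS = c(demo$ymrs[s], demo$ymrs[s] + demo$d_ymrs[s]),
      CGAS = c(demo$cgas[s], demo$cgas[s] + demo$d_cgas[s]),
      ERC = c(demo$erc[s], demo$erc[s] + sub$d_erc),
      stringsAsFactors = FALSE)
  }))
  truth <- list(
    planted_edges = pe,
    planted_edge_names = cbind(atlas$roi_name[pe[, 1L]],
                               atlas$roi_name[pe[, 2L]]),
    planted_subnetwork = spec$planted_subnetwork,
    delta = spec$effect_size, beta = spec$clinical_beta, seed = spec$seed)
  structure(list(atlas = atlas, spec = spec, subjects = subjects,
                 clinical = clinical, truth = truth),
            class = "conntop_cohort")
}

#' @export
print.conntop_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(x$subjects), "subjects x 2 sessions,",
      x$spec$n_timepoints, "time points x", nrow(x$atlas), "ROIs\n")
  cat("planted:", nrow(x$truth$planted_edges), "edge(s) in",
      x$truth$planted_subnetwork, "at delta =", x$truth$delta, "\n")
  invisible(x)
}

#' Per-session connectivity matrices for a cohort
#'
#' Convenience wrapper running [compute_connectivity()] (and optionally
#' [extract_subnetwork()]) on every subject-session.
#'
#' @param cohort A `conntop_cohort`.
#' @param label Optional subnetwork label to extract.
#' @return List with `pre` and `post`: lists of connectivity matrices aligned
#'   by subject.
#' @export
cohort_connectivity <- function(cohort, label = NULL) {
  one <- function(ts) {
    cm <- compute_connectivity(ts)
    if (is.null(label)) cm else extract_subnetwork(cm, cohort$atlas, label)
  }
  list(pre = lapply(cohort$subjects, function(s) one(s$pre)),
       post = lapply(cohort$subjects, function(s) one(s$post)))
}

#' Write a cohort to the on-disk TSV layout
#'
#' Writes `atlas.tsv`, one `<subject>_<pre|post>.tsv` time-series file per
#' subject-session, `clinical.tsv`, and `truth.json` (planted edges, delta,
#' beta, seed).
#'
#' @param cohort A `conntop_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  for (sub in cohort$subjects) {
    write_timeseries(sub$pre, file.path(dir, paste0(sub$id, "_pre.tsv")))
    write_timeseries(sub$post, file.path(dir, paste0(sub$id, "_post.tsv")))
  }
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$planted_edges <- apply(truth$planted_edges, 1L, identity,
                               simplify = FALSE)
  truth$planted_edge_names <- apply(truth$planted_edge_names, 1L, identity,
                                    simplify = FALSE)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the TSV layout.
#' @return List with `atlas`, `subjects` (id, pre, post matrices), and
#'   `clinical`.
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  ids <- unique(clinical$subject)
  subjects <- lapply(ids, function(id) {
    list(id = id,
         pre = read_timeseries(file.path(dir, paste0(id, "_pre.tsv")),
                               atlas = atlas),
         post = read_timeseries(file.path(dir, paste0(id, "_post.tsv")),
                                atlas = atlas))
  })
  names(subjects) <- ids
  list(atlas = atlas, subjects = subjects, clinical = clinical)
}

#' Band-pass and detrend utility for synthetic series
#'
#' Light frequency-domain cleanup for simulated data only: removes a linear
#' trend per column and zeroes Fourier components outside `[f_lo, f_hi]`
#' (cycles per sample). The analysis pipeline otherwise consumes
#' already-preprocessed time series as given.
#'
#' @param ts T x N numeric matrix.
#' @param f_lo,f_hi Pass band in cycles per sample (defaults emulate a
#'   0.01-0.08 Hz band at a 3 s sampling interval: 0.03-0.24 cycles/sample).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_detrend <- function(ts, f_lo = 0.03, f_hi = 0.24) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  tt <- seq_len(n_t)
  ts <- apply(ts, 2L, function(col) stats::resid(stats::lm.fit(
    cbind(1, tt), col)))
  freq <- c(0, seq_len(n_t - 1)) / n_t
  freq <- pmin(freq, 1 - freq)
  keep <- freq >= f_lo & freq <= f_hi
  out <- apply(ts, 2L, function(col) {
    sp <- stats::fft(col)
    sp[!keep] <- 0
    Re(stats::fft(sp, inverse = TRUE)) / n_t
  })
  matrix(out, n_t, ncol(ts), dimnames = dimnames(ts))
}
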