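#' Read an ROI time-series matrix
#'
#' Reads a delimited numeric matrix with time points in rows and ROIs in
#' columns (one file per subject-session). The column count must match the
#' atlas when one is supplied; column order is taken to be atlas order.
#' Transposed input (ROIs in rows) is only accepted via the explicit
#' `transposed` flag, never guessed from the shape.
#'
#' @param path Path to a delimited numeric text file without header.
#' @param atlas Optional `conntop_atlas`; enforces the ROI count and attaches
#'   `roi_name` column names.
#' @param sep Field separator (tab by default).
#' @param transposed Set `TRUE` if the file stores ROIs in rows.
#' @return Numeric matrix, time points x ROIs.
#' @export
read_timeseries <- function(path, atlas = NULL, sep = "\t",
                            transposed = FALSE) {
  raw <- utils::read.delim(path, sep = sep, header = FALSE,
                           colClasses = "character")
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d, column %d of '%s'",
                 bad[1L], bad[2L], path), call. = FALSE)
  }
  if (transposed) mat <- t(mat)
  if (!is.null(atlas)) {
    if (ncol(mat) != nrow(atlas)) {
      stop(sprintf(
        "time series has %d columns but atlas defines %d ROIs ('%s')",
        ncol(mat), nrow(atlas), path), call. = FALSE)
    }
    colnames(mat) <- atlas$roi_name
  }
  mat
}

#' Write an ROI time-series matrix
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip is the identity well past the documented 12-digit guarantee.
#'
#' @param mat Numeric matrix, time points x ROIs.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(mat, path, sep = "\t") {
  txt <- apply(mat, 1L, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Read a long-format clinical score table
#'
#' One row per subject-session keeps the paired structure explicit. Expected
#' header: `subject`, `session`, `age`, `sex`, then one column per clinical
#' scale (`CDRS_R`, `YMRS`, `CGAS`, `ERC` in the default layout).
#'
#' @param path Path to a delimited file with header.
#' @param sep Field separator.
#' @return Data frame with `session` checked against `c("pre", "post")` and
#'   every subject present in both sessions.
#' @export
read_clinical <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("subject", "session")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("clinical table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$session %in% c("pre", "post"))) {
    stop("clinical 'session' must be 'pre' or 'post'", call. = FALSE)
  }
  tab <- table(df$subject, df$session)
  if (!all(tab == 1L)) {
    stop("every subject needs exactly one pre and one post row", call. = FALSE)
  }
  df$subject <- as.character(df$subject)
  df
}

#' Write a clinical score table
#' @param df Clinical data frame (long format).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable results report
#'
#' Serializes pipeline results (metric AUC tables, permutation test results,
#' NBS components as `roi_name` edge lists) to JSON. Objects with an
#' [as_report()] method are converted first; the written structure is
#' recovered exactly by [read_report()].
#'
#' @param results A result object or named list of result objects.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  payload <- as_report(results)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write report to '", path, "': ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), con)
  invisible(path)
}

#' Read back a results report written by [write_report()]
#' @param path Path to the JSON report.
#' @return The report as nested lists.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Convert a result object to a plain report structure
#'
#' @param x A result object (`nbs_result`, `perm_test`, or plain list).
#' @param ... Passed to methods.
#' @return Nested lists/vectors suitable for JSON serialization.
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.default <- function(x, ...) {
  if (is.list(x)) lapply(x, as_report) else x
}

#' @export
as_report.nbs_result <- function(x, ...) {
  comps <- lapply(x$components, function(cp) {
    list(nodes = cp$nodes,
         edges = lapply(seq_len(nrow(cp$edges)), function(i)
           c(cp$edges[i, 1L], cp$edges[i, 2L])),
         size = cp$size,
         n_nodes = length(cp$nodes),
         mean_t = cp$mean_t,
         direction = cp$direction,
         fwe_p = cp$fwe_p)
  })
  list(components = comps,
       n_suprathreshold_edges = x$n_suprathreshold,
       primary_alpha = x$primary_alpha,
       n_perm = x$n_perm,
       method = x$method,
       seed = x$seed)
}

#' @export
as_report.perm_test <- function(x, ...) {
  list(observed = x$observed, p = x$p, n_perm = x$n_perm,
       method = x$method, seed = x$seed)
}
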