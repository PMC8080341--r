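#' Read an ROI atlas definition
#'
#' An atlas defines the nodes of the functional network: one row per region of
#' interest (ROI), with a name, stereotaxic coordinates (mm, informational
#' only) and the intrinsic subnetwork the region belongs to (e.g. `"DMN"`,
#' `"FPN"`, `"CON"`, `"other"`). Node order is the file order and is preserved
#' by every downstream operation.
#'
#' @param path Path to a delimited text file with header columns `roi_name`,
#'   `x`, `y`, `z`, `subnetwork`.
#' @param sep Field separator; tab by default, use `","` for CSV.
#'
#' @return A data frame of class `conntop_atlas` with columns `roi_id`
#'   (1-based integer index in file order), `roi_name`, `x`, `y`, `z`,
#'   `subnetwork`.
#' @seealso [atlas_counts()], [extract_subnetwork()], [synthetic_atlas()]
#' @export
read_atlas <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("roi_name", "x", "y", "z", "subnetwork")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("atlas file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$roi_name)) {
    dup <- unique(df$roi_name[duplicated(df$roi_name)])
    stop("duplicated roi_name in atlas: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  as_atlas(df[required])
}

#' Construct an atlas object from a data frame
#'
#' @param df Data frame with columns `roi_name`, `x`, `y`, `z`, `subnetwork`.
#' @return A `conntop_atlas` data frame; see [read_atlas()].
#' @export
as_atlas <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("roi_name", "subnetwork") %in% names(df)))
  if (anyDuplicated(df$roi_name)) stop("duplicated roi_name", call. = FALSE)
  for (col in c("x", "y", "z")) if (is.null(df[[col]])) df[[col]] <- 0
  out <- data.frame(roi_id = seq_len(nrow(df)),
                    roi_name = as.character(df$roi_name),
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    z = as.numeric(df$z),
                    subnetwork = as.character(df$subnetwork),
                    stringsAsFactors = FALSE)
  class(out) <- c("conntop_atlas", "data.frame")
  out
}

#' Write an atlas definition to a delimited file
#'
#' @param atlas A `conntop_atlas` object.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, sep = "\t") {
  utils::write.table(atlas[c("roi_name", "x", "y", "z", "subnetwork")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count ROIs per subnetwork
#'
#' @param atlas A `conntop_atlas` object.
#' @return Named integer vector of node counts, in first-appearance order.
#' @export
atlas_counts <- function(atlas) {
  labs <- unique(atlas$subnetwork)
  stats::setNames(vapply(labs, function(l) sum(atlas$subnetwork == l),
                         integer(1)), labs)
}

#' ROI indices belonging to a subnetwork
#'
#' Order-stable: returned indices follow atlas (file) order restricted to the
#' label.
#'
#' @param atlas A `conntop_atlas` object.
#' @param label Subnetwork label.
#' @return Integer vector of 1-based ROI indices.
#' @export
atlas_rois <- function(atlas, label) {
  if (!label %in% atlas$subnetwork) {
    stop("unknown subnetwork '", label, "'; available: ",
         paste(unique(atlas$subnetwork), collapse = ", "), call. = FALSE)
  }
  which(atlas$subnetwork == label)
}

#' Synthetic atlas emulating a 160-ROI functional parcellation
#'
#' Builds an atlas with the subnetwork composition used throughout the
#' package's simulations: 34 default-mode (DMN), 21 fronto-parietal (FPN) and
#' 32 cingulo-opercular (CON) regions plus unlabeled remainder, mirroring the
#' Dosenbach-style functional ROI set. Coordinates are laid out on a
#' deterministic lattice; they are informational and never enter any
#' computation.
#'
#' @param n_dmn,n_fpn,n_con,n_other Number of ROIs per subnetwork.
#' @return A `conntop_atlas` object with `n_dmn + n_fpn + n_con + n_other`
#'   rows, grouped by subnetwork in DMN, FPN, CON, other order.
#' @export
synthetic_atlas <- function(n_dmn = 34, n_fpn = 21, n_con = 32, n_other = 73) {
  labs <- rep(c("DMN", "FPN", "CON", "other"),
              times = c(n_dmn, n_fpn, n_con, n_other))
  n <- length(labs)
  idx_in <- unlist(lapply(c(n_dmn, n_fpn, n_con, n_other), seq_len))
  # deterministic lattice coordinates, informational only
  g <- ceiling(n^(1 / 3))
  k <- seq_len(n) - 1L
  as_atlas(data.frame(
    roi_name = sprintf("%s_%02d", labs, idx_in),
    x = (k %% g) * 10 - 45,
    y = ((k %/% g) %% g) * 10 - 45,
    z = (k %/% (g * g)) * 10 - 45,
    subnetwork = labs,
    stringsAsFactors = FALSE))
}

#' @export
print.conntop_atlas <- function(x, ...) {
  cts <- atlas_counts(x)
  cat("ROI atlas:", nrow(x), "regions (",
      paste(sprintf("%s=%d", names(cts), cts), collapse = ", "), ")\n")
  NextMethod()
}
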