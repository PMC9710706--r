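#' Labeled features-by-samples omics matrix
#'
#' Constructs a validated numeric matrix with features in rows and samples in
#' columns, tagged with its role in the integration: `"linker"` features are
#' screened as putative confounders, `"vertex"` features become the nodes of
#' the output network.
#'
#' Validation enforces unique feature and sample identifiers and, by default,
#' drops (with a warning) any feature containing a non-finite value or having
#' zero sample variance; correlations are undefined for such features. With
#' `drop_invalid = FALSE` these conditions raise errors instead.
#'
#' @param values numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs).
#' @param role `"linker"` or `"vertex"`.
#' @param drop_invalid drop offending features (with a warning) rather than
#'   erroring.
#' @return an `omics_matrix`: the numeric matrix with attributes `role` and
#'   `dropped` (character vector of removed feature IDs).
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'   dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' om <- omics_matrix(m, role = "vertex")
#' @export
omics_matrix <- function(values, role = c("vertex", "linker"),
                         drop_invalid = TRUE) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (ncol(values) < 4L)
    stop("at least 4 samples are required (partial correlation is undefined below n = 4), got ",
         ncol(values))

  bad_finite <- !apply(values, 1L, function(x) all(is.finite(x)))
  vars <- apply(values, 1L, stats::var)
  bad_var <- !bad_finite & vars == 0
  dropped <- rownames(values)[bad_finite | bad_var]
  if (length(dropped)) {
    if (!drop_invalid)
      stop("invalid features (missing values or zero variance): ",
           paste(dropped, collapse = ", "))
    warning(sprintf("dropped %d %s feature(s) (%d with missing/non-finite values, %d with zero variance): %s",
                    length(dropped), role, sum(bad_finite), sum(bad_var),
                    paste(dropped, collapse = ", ")), call. = FALSE)
    values <- values[!(bad_finite | bad_var), , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no features left after validation")
  structure(values, role = role, dropped = dropped,
            class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix (role: %s): %d features x %d samples\n",
              attr(x, "role"), nrow(x), ncol(x)))
  dr <- attr(x, "dropped")
  if (length(dr)) cat(sprintf("  %d feature(s) dropped at validation\n", length(dr)))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- as_bare_matrix(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  y <- m[i, j, drop = drop]
  if (is.matrix(y)) {
    attr(y, "role") <- attr(x, "role")
    attr(y, "dropped") <- attr(x, "dropped")
    class(y) <- class(x)
  }
  y
}

# strip omics_matrix attributes, keep the bare named matrix
as_bare_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "role") <- NULL
  attr(y, "dropped") <- NULL
  y
}

matrix_role <- function(x) {
  r <- attr(x, "role")
  if (is.null(r)) "vertex" else r
}

#' Read a features-by-samples matrix from a delimited text file
#'
#' Expects the first row to hold sample IDs and the first column feature IDs
#' (the usual omics table layout). Features with missing values or zero
#' variance are dropped with a warning. Use `transpose = TRUE` for files with
#' samples in rows.
#'
#' @param path file path.
#' @param role `"linker"` or `"vertex"`.
#' @param sep field delimiter; default tab.
#' @param transpose set when the file stores samples in rows.
#' @return an [omics_matrix].
#' @seealso [write_omics_matrix()]
#' @export
read_omics_matrix <- function(path, role = c("vertex", "linker"), sep = "\t",
                              transpose = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("matrix file needs a feature-ID column plus data columns: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    vals <- apply(vals, c(1, 2), function(v) suppressWarnings(as.numeric(v)))
  }
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  omics_matrix(vals, role = role, drop_invalid = TRUE)
}

#' Write an omics matrix as delimited text
#'
#' Inverse of [read_omics_matrix()]: sample IDs in the header, feature IDs in
#' the first column (named `feature_id`). Round-trips values exactly via
#' maximum-precision decimal formatting.
#'
#' @param x matrix or [omics_matrix].
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_omics_matrix <- function(x, path, sep = "\t") {
  m <- as_bare_matrix(x)
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two matrices to their common samples
#'
#' The integration requires the linker and vertex data to cover the same
#' samples; this intersects the sample IDs and puts the shared columns in an
#' identical (first-matrix) order in both outputs.
#'
#' @param linker,vertex [omics_matrix] objects (or named matrices).
#' @return list with elements `linker` and `vertex`.
#' @export
align_samples <- function(linker, vertex) {
  common <- intersect(colnames(linker), colnames(vertex))
  if (length(common) == 0L) stop("no samples shared between the two matrices")
  if (length(common) < 4L)
    stop("only ", length(common), " shared sample(s); at least 4 are required")
  list(linker = linker[, common, drop = FALSE],
       vertex = vertex[, common, drop = FALSE])
}

#' Keep high-variance features
#'
#' The optional pre-filter (the "filter high-variance features" switch of the
#' integration) retains features whose sample variance is at or above the
#' `keep_quantile` quantile of all feature variances in the matrix, so
#' `keep_quantile = 0.75` keeps roughly the top quarter. Ties at the threshold
#' are all kept; `keep_quantile = 0` is a no-op.
#'
#' @param x matrix or [omics_matrix].
#' @param keep_quantile variance quantile in `[0, 1)` below which features are
#'   discarded.
#' @return the filtered matrix, same class as the input.
#' @export
filter_by_variance <- function(x, keep_quantile = 0.75) {
  if (!is.numeric(keep_quantile) || length(keep_quantile) != 1L ||
      keep_quantile < 0 || keep_quantile >= 1)
    stop("'keep_quantile' must be a single number in [0, 1)")
  if (keep_quantile == 0) return(x)
  vars <- apply(x, 1L, stats::var)
  thr <- stats::quantile(vars, keep_quantile, names = FALSE)
  keep <- vars >= thr
  message(sprintf("variance filter (quantile %.3g): retained %d of %d features",
                  keep_quantile, sum(keep), length(keep)))
  x[keep, , drop = FALSE]
}
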