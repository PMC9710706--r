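#' Triplets shared between two conditions
#'
#' Intersects the significant triplet sets of two integrations on the
#' canonical (vertex_a, vertex_b, linker) key and reports the per-condition
#' correlation, partial correlation and change side by side, together with
#' the Jaccard index of the two triplet sets. With `level = "edge"` sharing
#' is relaxed to the vertex pair irrespective of which linker confounds it.
#'
#' @param net_a,net_b `linkcor` objects or triplet data.frames (significant
#'   rows are used).
#' @param level `"triplet"` (exact (pair, linker) identity, default) or
#'   `"edge"` (shared vertex pair, any linker).
#' @return object of class `linkcor_comparison`: list with the `shared`
#'   data.frame, `jaccard`, and the two set sizes `n_a`, `n_b`.
#' @export
shared_triplets <- function(net_a, net_b, level = c("triplet", "edge")) {
  level <- match.arg(level)
  ta <- sig_table(net_a); tb <- sig_table(net_b)
  key <- function(d) if (level == "triplet")
    paste(d$vertex_a, d$vertex_b, d$linker, sep = "\r")
  else paste(d$vertex_a, d$vertex_b, sep = "\r")
  ka <- key(ta); kb <- key(tb)
  ua <- unique(ka); ub <- unique(kb)
  shared_keys <- sort(intersect(ua, ub))
  ia <- match(shared_keys, ka); ib <- match(shared_keys, kb)
  shared <- data.frame(vertex_a = ta$vertex_a[ia], vertex_b = ta$vertex_b[ia],
                       stringsAsFactors = FALSE)
  if (level == "triplet") shared$linker <- ta$linker[ia]
  for (v in c("r", "r_partial", "delta")) {
    shared[[paste0(v, "_a")]] <- ta[[v]][ia]
    shared[[paste0(v, "_b")]] <- tb[[v]][ib]
  }
  un <- union(ua, ub)
  structure(list(shared = shared,
                 jaccard = if (length(un)) length(shared_keys) / length(un) else 0,
                 n_a = length(ua), n_b = length(ub), level = level),
            class = "linkcor_comparison")
}

#' @export
print.linkcor_comparison <- function(x, ...) {
  cat(sprintf("shared %ss: %d (condition A: %d, condition B: %d), Jaccard %.3f\n",
              x$level, nrow(x$shared), x$n_a, x$n_b, x$jaccard))
  invisible(x)
}

#' Read a vertex-class annotation table
#'
#' Two-column delimited file mapping vertex feature IDs to class labels
#' (e.g. lipid class or pathway); columns `feature_id` and `class` (header
#' optional, first two columns used).
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return named character vector (feature ID -> class).
#' @export
read_class_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("class map needs two columns (feature_id, class)")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature IDs in class map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Class-pair summary of shared confounding
#'
#' Counts the triplets shared between two conditions, grouped by the
#' unordered pair of vertex classes, for linkers present in both networks.
#' Vertices without a class annotation are reported as `"unclassified"`.
#' The long-format output plots directly as (stacked) bars.
#'
#' @param net_a,net_b `linkcor` objects or triplet data.frames.
#' @param classes named character vector mapping vertex feature IDs to class
#'   labels (see [read_class_map()]); may be partial.
#' @return data.frame with `class_a`, `class_b` (`class_a <= class_b`),
#'   `n_shared_triplets`, `n_linkers`.
#' @export
shared_linker_summary <- function(net_a, net_b, classes) {
  cmp <- shared_triplets(net_a, net_b, level = "triplet")
  sh <- cmp$shared
  empty <- data.frame(class_a = character(), class_b = character(),
                      n_shared_triplets = integer(), n_linkers = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sh) == 0L) return(empty)
  cls <- function(id) {
    out <- unname(classes[id])
    out[is.na(out)] <- "unclassified"
    out
  }
  ca <- cls(sh$vertex_a); cb <- cls(sh$vertex_b)
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  key <- paste(lo, hi, sep = "\r")
  sp <- split(seq_len(nrow(sh)), key)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(class_a = lo[i[1L]], class_b = hi[i[1L]],
               n_shared_triplets = length(i),
               n_linkers = length(unique(sh$linker[i])),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$class_a, out$class_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
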