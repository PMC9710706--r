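#' Confounder triplet screening across two paired omics datasets
#'
#' The core integration. For every retained pair of vertex features (a, b)
#' and every linker feature l, the zero-order correlation r(a, b) is compared
#' with the first-order partial correlation r(a, b | l) via a Steiger-type Z
#' test for dependent correlations (see [steiger_test()]). Benjamini-Hochberg
#' adjustment is applied across all tested triplets; a significant triplet
#' marks l as a putative confounder of the a-b relationship and contributes
#' an edge to the integrated network.
#'
#' By default the vertex pair set is first sparsified to the significantly
#' correlated pairs ([significant_pairs()]), which both focuses the screen on
#' meaningful vertex relationships and reduces the O(m^2/2 * p) triplet count.
#' An optional variance pre-filter (`fhvf`) restricts the linker features
#' (optionally also the vertex features) to the high-variance quantile before
#' anything is computed.
#'
#' Triplets whose linker shares its feature ID with either vertex feature are
#' degenerate (a variable cannot confound itself) and are skipped and counted.
#' Computation is streamed over chunks of vertex pairs with per-triplet
#' scalar algebra, so memory stays bounded in the linker count; results are
#' identical for any chunk size or worker count.
#'
#' @param vertex vertex dataset: [omics_matrix] or named numeric matrix,
#'   features x samples. Its features become network nodes.
#' @param linker linker dataset, same samples; its features are screened as
#'   confounders.
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @param alpha_pair significance level for the vertex-pair sparsification.
#' @param alpha_triplet significance level on BH-adjusted Steiger p-values.
#' @param sparsify_pairs restrict testing to significantly correlated vertex
#'   pairs (default) or test all pairs.
#' @param use_adjusted_pairs sparsify on BH-adjusted pair p-values (default)
#'   rather than raw.
#' @param sparsify_partial additionally require the partial correlation
#'   itself to be significant at `alpha_pair` (t test, n - 3 df) for a
#'   triplet to enter the BH pool; off by default.
#' @param fhvf apply the high-variance pre-filter ([filter_by_variance()]).
#' @param fhvf_quantile variance quantile for the pre-filter.
#' @param fhvf_target which matrix the pre-filter applies to:
#'   `"linker"` (default), `"vertex"`, or `"both"`.
#' @param workers chunks may be evaluated with this many forked workers
#'   (unix); results are independent of the setting.
#' @param chunk_size vertex pairs per chunk.
#' @param max_triplets guard: error if pairs x linkers exceeds this cap.
#' @return object of class `linkcor`; see [triplets()], [significant_triplets()],
#'   [rank_linkers()], [as_weighted_graph()].
#' @examples
#' sim <- simulate_latent_datasets(n_samples = 40, p_linker = 5,
#'                                 m_vertex = 8, seed = 1)
#' fit <- linkcor(sim$vertex, sim$linker, sparsify_pairs = FALSE)
#' fit
#' @export
linkcor <- function(vertex, linker,
                 method = c("pearson", "spearman"),
                 alpha_pair = 0.05,
                 alpha_triplet = 0.05,
                 sparsify_pairs = TRUE,
                 use_adjusted_pairs = TRUE,
                 sparsify_partial = FALSE,
                 fhvf = FALSE,
                 fhvf_quantile = 0.75,
                 fhvf_target = c("linker", "vertex", "both"),
                 workers = 1L,
                 chunk_size = 512L,
                 max_triplets = 1e8) {
  method <- match.arg(method)
  fhvf_target <- match.arg(fhvf_target)
  for (a in list(alpha_pair, alpha_triplet))
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
      stop("significance levels must be single numbers in (0, 1)")

  V <- if (inherits(vertex, "omics_matrix")) vertex else
    omics_matrix(as.matrix(vertex), role = "vertex")
  L <- if (inherits(linker, "omics_matrix")) linker else
    omics_matrix(as.matrix(linker), role = "linker")
  al <- align_samples(L, V)
  L <- al$linker; V <- al$vertex
  n <- ncol(V)

  if (fhvf) {
    if (fhvf_target %in% c("linker", "both"))
      L <- filter_by_variance(L, fhvf_quantile)
    if (fhvf_target %in% c("vertex", "both"))
      V <- filter_by_variance(V, fhvf_quantile)
  }

  ct <- correlation_matrix(V, method = method)
  n_pairs_total <- nrow(ct$r) * (nrow(ct$r) - 1L) / 2L
  pairs <- if (sparsify_pairs)
    significant_pairs(ct, alpha = alpha_pair, use_adjusted = use_adjusted_pairs)
  else
    all_pairs(ct)

  counts <- list(m_vertex = nrow(V), p_linker = nrow(L), n_samples = n,
                 n_pairs_total = n_pairs_total, n_pairs_tested = nrow(pairs),
                 n_triplets_tested = 0L, n_collisions_skipped = 0L,
                 n_partial_sparsified = 0L, n_significant = 0L)
  settings <- list(method = method, alpha_pair = alpha_pair,
                   alpha_triplet = alpha_triplet,
                   sparsify_pairs = sparsify_pairs,
                   use_adjusted_pairs = use_adjusted_pairs,
                   sparsify_partial = sparsify_partial,
                   fhvf = fhvf, fhvf_quantile = fhvf_quantile,
                   fhvf_target = fhvf_target)

  if (nrow(pairs) == 0L) {
    message("no vertex pairs retained after sparsification; empty result")
    return(new_linkcor(empty_triplet_table(), counts, settings,
                    rownames(V), rownames(L), match.call()))
  }
  if (as.double(nrow(pairs)) * nrow(L) > max_triplets)
    stop("pairs x linkers = ", nrow(pairs) * nrow(L),
         " exceeds max_triplets = ", max_triplets)

  Cvl <- stats::cor(t(as_bare_matrix(V)), t(as_bare_matrix(L)), method = method)
  linker_ids <- rownames(L)
  chunks <- split(seq_len(nrow(pairs)),
                  ceiling(seq_len(nrow(pairs)) / max(1L, chunk_size)))
  eval_chunk <- function(idx) {
    a <- pairs$feature_a[idx]; b <- pairs$feature_b[idx]
    P <- length(idx); p <- length(linker_ids)
    rxy <- matrix(pairs$r[idx], P, p)
    rxz <- Cvl[a, , drop = FALSE]
    ryz <- Cvl[b, , drop = FALSE]
    st <- steiger_from_correlations(rxy, rxz, ryz, n)
    data.frame(vertex_a = rep(a, p), vertex_b = rep(b, p),
               linker = rep(linker_ids, each = P),
               r = as.vector(rxy), r_partial = as.vector(st$r_partial),
               delta = as.vector(st$delta), z = as.vector(st$z),
               p_raw = as.vector(st$p), stringsAsFactors = FALSE)
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(chunks, eval_chunk, mc.cores = workers)
  else lapply(chunks, eval_chunk)
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL

  collision <- tab$linker == tab$vertex_a | tab$linker == tab$vertex_b
  counts$n_collisions_skipped <- sum(collision)
  tab <- tab[!collision, , drop = FALSE]

  if (sparsify_partial) {
    pp <- cor_pvalue(clamp_r(tab$r_partial), n - 1L)  # n-3 df via n' - 2
    keep <- pp < alpha_pair
    counts$n_partial_sparsified <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
  }

  counts$n_triplets_tested <- nrow(tab)
  tab$p_adj <- stats::p.adjust(tab$p_raw, method = "BH")
  tab$sign <- ifelse(abs(tab$r_partial) > abs(tab$r), "strengthens", "weakens")
  tab$significant <- tab$p_adj < alpha_triplet
  counts$n_significant <- sum(tab$significant)
  tab <- tab[order(tab$vertex_a, tab$vertex_b, tab$linker), triplet_columns(),
             drop = FALSE]
  rownames(tab) <- NULL
  new_linkcor(tab, counts, settings, rownames(V), rownames(L), match.call())
}

triplet_columns <- function() {
  c("vertex_a", "vertex_b", "linker", "r", "r_partial", "delta", "sign",
    "z", "p_raw", "p_adj", "significant")
}

empty_triplet_table <- function() {
  data.frame(vertex_a = character(), vertex_b = character(),
             linker = character(), r = numeric(), r_partial = numeric(),
             delta = numeric(), sign = character(), z = numeric(),
             p_raw = numeric(), p_adj = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

new_linkcor <- function(triplets, counts, settings, vertex_ids, linker_ids, call) {
  structure(list(triplets = triplets, counts = counts, settings = settings,
                 n_samples = counts$n_samples, vertex_ids = vertex_ids,
                 linker_ids = linker_ids, call = call),
            class = "linkcor")
}

#' Full triplet table of a fitted integration
#'
#' One row per tested (vertex pair, linker) triplet with the zero-order
#' correlation `r`, partial correlation `r_partial`, absolute change `delta`,
#' direction `sign` (whether conditioning strengthens or weakens the
#' association in magnitude), Steiger statistic `z`, raw and BH-adjusted
#' p-values, and the significance flag.
#'
#' @param x a `linkcor` object.
#' @return data.frame in canonical order (vertex_a < vertex_b, rows sorted
#'   by vertex_a, vertex_b, linker).
#' @export
triplets <- function(x) {
  stopifnot(inherits(x, "linkcor"))
  x$triplets
}

#' Significant confounder triplets
#'
#' @param x a `linkcor` object.
#' @return the rows of [triplets()] flagged significant.
#' @export
significant_triplets <- function(x) {
  tt <- triplets(x)
  tt[tt$significant, , drop = FALSE]
}

#' Rank linker features by their strongest correlation change
#'
#' Linkers are ordered by the maximum `delta` (absolute difference between
#' partial and zero-order correlation) over their significant triplets —
#' large values reflect a stronger effect on a vertex-pair relationship —
#' with mean delta, then feature ID, as tie-breaks.
#'
#' @param x `linkcor` object or a triplet data.frame.
#' @param top_k optionally truncate to the first `top_k` linkers.
#' @return data.frame with `linker`, `n_triplets`, `max_delta`, `mean_delta`.
#' @export
rank_linkers <- function(x, top_k = NULL) {
  tt <- if (inherits(x, "linkcor")) significant_triplets(x) else
    x[x$significant, , drop = FALSE]
  if (nrow(tt) == 0L)
    return(data.frame(linker = character(), n_triplets = integer(),
                      max_delta = numeric(), mean_delta = numeric(),
                      stringsAsFactors = FALSE))
  sp <- split(tt$delta, tt$linker)
  out <- data.frame(linker = names(sp),
                    n_triplets = vapply(sp, length, 1L),
                    max_delta = vapply(sp, max, 1.0),
                    mean_delta = vapply(sp, mean, 1.0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$max_delta, -out$mean_delta, out$linker), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' @export
print.linkcor <- function(x, ...) {
  cat("Confounder triplet screen\n")
  with(x$counts, {
    cat(sprintf("  vertex features: %d, linker features: %d, samples: %d\n",
                m_vertex, p_linker, n_samples))
    cat(sprintf("  vertex pairs tested: %d of %d\n", n_pairs_tested, n_pairs_total))
    cat(sprintf("  triplets tested: %d (skipped %d ID collisions)\n",
                n_triplets_tested, n_collisions_skipped))
    cat(sprintf("  significant triplets (BH < %g): %d\n",
                x$settings$alpha_triplet, n_significant))
  })
  invisible(x)
}

#' @export
summary.linkcor <- function(object, top_k = 5L, ...) {
  sig <- significant_triplets(object)
  structure(list(counts = object$counts, settings = object$settings,
                 n_vertex_in_network = length(unique(c(sig$vertex_a, sig$vertex_b))),
                 n_linkers_in_network = length(unique(sig$linker)),
                 top_linkers = rank_linkers(object, top_k = top_k)),
            class = "summary.linkcor")
}

#' @export
print.summary.linkcor <- function(x, ...) {
  cat("Confounder triplet screen summary\n")
  cat(sprintf("  significant triplets: %d (of %d tested)\n",
              x$counts$n_significant, x$counts$n_triplets_tested))
  cat(sprintf("  network: %d vertex nodes, %d confounding linkers\n",
              x$n_vertex_in_network, x$n_linkers_in_network))
  if (nrow(x$top_linkers)) {
    cat("  top linkers by max |correlation change|:\n")
    print(x$top_linkers, digits = 3)
  }
  invisible(x)
}

#' Write / read a triplet table as TSV
#'
#' Column order and numeric formatting are fixed so the file round-trips
#' losslessly and reruns are byte-identical.
#'
#' @param x `linkcor` object or triplet data.frame.
#' @param path file path.
#' @export
write_triplets <- function(x, path) {
  tt <- if (inherits(x, "linkcor")) triplets(x) else x
  tt <- tt[, triplet_columns(), drop = FALSE]
  num <- vapply(tt, is.numeric, TRUE)
  tt[num] <- lapply(tt[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  tt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(triplet_columns(), names(tt))
  if (length(missing))
    stop("triplet table ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  tt$significant <- as.logical(tt$significant)
  tt[, triplet_columns(), drop = FALSE]
}
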