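#' Integration run configuration
#'
#' Bundles every knob of the end-to-end run into one validated list that
#' serializes to and from a single YAML document. Unknown keys are rejected
#' so configuration typos fail loudly.
#'
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param alpha_pair,alpha_triplet significance levels for the pair
#'   sparsification and the triplet screen.
#' @param sparsify_pairs,sparsify_partial,use_adjusted_pairs sparsification
#'   switches, see [linkcor()].
#' @param fhvf,fhvf_quantile,fhvf_target variance pre-filter settings.
#' @param workers,chunk_size execution knobs (results are independent of
#'   both).
#' @param transpose input files store samples in rows.
#' @param delimiter input field delimiter.
#' @param seed master seed recorded in the manifest (the integration itself
#'   is deterministic).
#' @return object of class `linkcor_config` (a named list).
#' @export
linkcor_config <- function(correlation_method = "pearson", alpha_pair = 0.05,
                        alpha_triplet = 0.05, sparsify_pairs = TRUE,
                        use_adjusted_pairs = TRUE, sparsify_partial = FALSE,
                        fhvf = FALSE, fhvf_quantile = 0.75,
                        fhvf_target = "linker", workers = 1L,
                        chunk_size = 512L, transpose = FALSE,
                        delimiter = "\t", seed = 1L) {
  cfg <- list(correlation_method = correlation_method,
              alpha_pair = alpha_pair, alpha_triplet = alpha_triplet,
              sparsify_pairs = sparsify_pairs,
              use_adjusted_pairs = use_adjusted_pairs,
              sparsify_partial = sparsify_partial, fhvf = fhvf,
              fhvf_quantile = fhvf_quantile, fhvf_target = fhvf_target,
              workers = as.integer(workers), chunk_size = as.integer(chunk_size),
              transpose = transpose, delimiter = delimiter,
              seed = as.integer(seed))
  class(cfg) <- "linkcor_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file with a subset of the [linkcor_config()] keys; unknown
#'   keys raise an error.
#' @return a `linkcor_config`.
#' @export
read_linkcor_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(linkcor_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(linkcor_config, raw)
}

#' @rdname read_linkcor_config
#' @param cfg a `linkcor_config`.
#' @export
write_linkcor_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.linkcor_config <- function(x, ...) {
  cat("integration configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_digest <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' End-to-end integration run with file outputs
#'
#' Reads the two matrices, runs [linkcor()], and writes every standard output
#' to `out_dir`: the full triplet table (`triplets.tsv`), the weighted and
#' bipartite GraphML views, the hypergraph incidence matrix
#' (`incidence.tsv`), node/edge network statistics, the linker ranking, and
#' a YAML run manifest with the configuration digest, input hashes, package
#' version and the counts at every filtering stage. Outputs are
#' deterministic: rerunning with identical inputs and configuration
#' reproduces every file byte for byte. When no triplet is significant the
#' graph outputs are skipped (recorded in the manifest).
#'
#' @param vertex_path,linker_path delimited matrix files
#'   (see [read_omics_matrix()]).
#' @param out_dir output directory, created if needed.
#' @param config a [linkcor_config()].
#' @return the fitted `linkcor` object, invisibly.
#' @export
linkcor_run <- function(vertex_path, linker_path, out_dir,
                     config = linkcor_config()) {
  stopifnot(inherits(config, "linkcor_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vertex <- read_omics_matrix(vertex_path, role = "vertex",
                              sep = config$delimiter,
                              transpose = config$transpose)
  linker <- read_omics_matrix(linker_path, role = "linker",
                              sep = config$delimiter,
                              transpose = config$transpose)
  fit <- linkcor(vertex, linker,
              method = config$correlation_method,
              alpha_pair = config$alpha_pair,
              alpha_triplet = config$alpha_triplet,
              sparsify_pairs = config$sparsify_pairs,
              use_adjusted_pairs = config$use_adjusted_pairs,
              sparsify_partial = config$sparsify_partial,
              fhvf = config$fhvf, fhvf_quantile = config$fhvf_quantile,
              fhvf_target = config$fhvf_target,
              workers = config$workers, chunk_size = config$chunk_size)

  write_triplets(fit, file.path(out_dir, "triplets.tsv"))
  rk <- rank_linkers(fit)
  utils::write.table(rk, file.path(out_dir, "linker_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  has_network <- fit$counts$n_significant > 0L
  if (has_network) {
    gw <- as_weighted_graph(fit)
    write_graphml(gw, file.path(out_dir, "weighted.graphml"))
    write_graphml(as_bipartite_graph(fit), file.path(out_dir, "bipartite.graphml"))
    inc <- incidence_matrix(fit)
    utils::write.table(
      data.frame(vertex = rownames(inc), inc, check.names = FALSE),
      file.path(out_dir, "incidence.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    st <- network_statistics(gw)
    for (part in c("nodes", "edges")) {
      d <- st[[part]]
      num <- vapply(d, is.numeric, TRUE)
      d[num] <- lapply(d[num], function(v) format(v, digits = 17, trim = TRUE))
      utils::write.table(d, file.path(out_dir, paste0(part, "_stats.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(
    config = unclass(config),
    config_digest = config_digest(config),
    inputs = list(
      vertex = list(path = normalizePath(vertex_path),
                    md5 = unname(tools::md5sum(vertex_path))),
      linker = list(path = normalizePath(linker_path),
                    md5 = unname(tools::md5sum(linker_path)))),
    package_version = as.character(utils::packageVersion("linkcor")),
    counts = fit$counts,
    network_written = has_network)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(fit)
}

#' Cross-condition comparison with file outputs
#'
#' Reads two triplet tables (as written by [linkcor_run()]), intersects their
#' significant triplets, and writes `shared_triplets.tsv` plus a YAML
#' summary with the Jaccard index; with a vertex-class map it also writes
#' the class-pair summary `shared_class_summary.tsv`.
#'
#' @param triplets_a,triplets_b triplet TSV paths.
#' @param out_dir output directory.
#' @param classes_path optional class-map TSV ([read_class_map()]).
#' @return the `linkcor_comparison`, invisibly.
#' @export
linkcor_compare <- function(triplets_a, triplets_b, out_dir,
                         classes_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ta <- read_triplets(triplets_a)
  tb <- read_triplets(triplets_b)
  cmp <- shared_triplets(ta, tb)
  sh <- cmp$shared
  num <- vapply(sh, is.numeric, TRUE)
  sh[num] <- lapply(sh[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(sh, file.path(out_dir, "shared_triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(n_shared = nrow(cmp$shared), jaccard = cmp$jaccard,
                  n_a = cmp$n_a, n_b = cmp$n_b)
  if (!is.null(classes_path)) {
    classes <- read_class_map(classes_path)
    cls <- shared_linker_summary(ta, tb, classes)
    utils::write.table(cls, file.path(out_dir, "shared_class_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_class_pairs <- nrow(cls)
  }
  yaml::write_yaml(summary, file.path(out_dir, "comparison.yaml"))
  invisible(cmp)
}
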