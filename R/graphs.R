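#' Weighted undirected network of vertex features
#'
#' Collapses the significant triplets into the primary network view: nodes
#' are vertex features, and two nodes are joined when at least one linker
#' significantly confounds their correlation. The edge weight is the number
#' of distinct confounding linkers; the linker IDs and the maximum and mean
#' correlation change are stored as edge attributes, so the significant
#' triplet set is fully reconstructible from this view.
#'
#' @param x `linkcor` object or a triplet data.frame (its significant rows are
#'   used).
#' @return an [igraph][igraph::igraph-package] undirected graph with edge
#'   attributes `weight`, `linkers` (comma-separated, sorted), `max_delta`,
#'   `mean_delta`.
#' @export
as_weighted_graph <- function(x) {
  tt <- sig_table(x)
  if (nrow(tt) == 0L) stop("no significant triplets; network is empty")
  key <- paste(tt$vertex_a, tt$vertex_b, sep = "\r")
  sp <- split(tt, key)
  edges <- do.call(rbind, lapply(sp, function(d) {
    data.frame(from = d$vertex_a[1L], to = d$vertex_b[1L],
               weight = length(unique(d$linker)),
               linkers = paste(sort(unique(d$linker)), collapse = ","),
               max_delta = max(d$delta), mean_delta = mean(d$delta),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- sort(unique(c(tt$vertex_a, tt$vertex_b)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Bipartite linker-vertex network
#'
#' Second network view: vertex features form one node class (`type = FALSE`)
#' and confounding linkers the other (`type = TRUE`); a linker is connected
#' to every vertex feature appearing in at least one of its significant
#' triplets. There are no within-class edges.
#'
#' @inheritParams as_weighted_graph
#' @return a bipartite igraph graph; edge attribute `n_triplets` counts the
#'   significant triplets behind each linker-vertex incidence.
#' @export
as_bipartite_graph <- function(x) {
  tt <- sig_table(x)
  if (nrow(tt) == 0L) stop("no significant triplets; network is empty")
  long <- rbind(data.frame(linker = tt$linker, vertex = tt$vertex_a,
                           stringsAsFactors = FALSE),
                data.frame(linker = tt$linker, vertex = tt$vertex_b,
                           stringsAsFactors = FALSE))
  key <- paste(long$linker, long$vertex, sep = "\r")
  cnt <- table(key)
  uniq <- long[!duplicated(key), , drop = FALSE]
  uniq$n_triplets <- as.integer(cnt[paste(uniq$linker, uniq$vertex, sep = "\r")])
  uniq <- uniq[order(uniq$linker, uniq$vertex), , drop = FALSE]
  vnodes <- sort(unique(long$vertex))
  lnodes <- sort(unique(long$linker))
  verts <- data.frame(name = c(vnodes, lnodes),
                      type = c(rep(FALSE, length(vnodes)), rep(TRUE, length(lnodes))),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = uniq$linker, to = uniq$vertex,
               n_triplets = uniq$n_triplets, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Hypergraph incidence matrix
#'
#' Third network view: each confounding linker is a hyperedge joining all
#' vertex features it confounds. Encoded as a 0/1 matrix with vertex
#' features in rows and linkers in columns (both sorted); entry 1 means the
#' vertex participates in at least one significant triplet of that linker.
#' Every column has at least two ones, since a triplet involves two vertices.
#'
#' @inheritParams as_weighted_graph
#' @return integer 0/1 matrix.
#' @export
incidence_matrix <- function(x) {
  tt <- sig_table(x)
  if (nrow(tt) == 0L) stop("no significant triplets; network is empty")
  vnodes <- sort(unique(c(tt$vertex_a, tt$vertex_b)))
  lnodes <- sort(unique(tt$linker))
  M <- matrix(0L, length(vnodes), length(lnodes),
              dimnames = list(vnodes, lnodes))
  M[cbind(match(c(tt$vertex_a, tt$vertex_b), vnodes),
          match(c(tt$linker, tt$linker), lnodes))] <- 1L
  M
}

sig_table <- function(x) {
  tt <- if (inherits(x, "linkcor")) triplets(x) else x
  tt[tt$significant, , drop = FALSE]
}

#' Default network statistics
#'
#' Per node: degree, weighted degree (strength), HITS hub score (for an
#' undirected graph the hub and authority scores coincide with the principal
#' adjacency eigenvector, normalized to a maximum of 1; edge weights act as
#' affinities) and betweenness centrality (unnormalized shortest-path pair
#' counts on the unweighted topology — the confounder-count weights are
#' affinities, not distances). Per edge: edge betweenness, also on the
#' unweighted topology. The node degree distribution is included.
#'
#' @param g an undirected igraph graph, e.g. from [as_weighted_graph()].
#' @return object of class `linkcor_network_stats`: list with data.frames
#'   `nodes`, `edges` and `degree_distribution`.
#' @export
network_statistics <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) < 1L) stop("graph has no edges")
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  deg <- igraph::degree(g)
  stre <- igraph::strength(g, weights = w)
  hub <- hub_scores(g, w)
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  el <- igraph::as_edgelist(g)
  ebt <- igraph::edge_betweenness(g, weights = NA)
  dd <- as.data.frame(table(degree = deg), stringsAsFactors = FALSE)
  names(dd) <- c("degree", "n_nodes")
  dd$degree <- as.integer(dd$degree)
  structure(list(
    nodes = data.frame(node = igraph::V(g)$name, degree = deg,
                       strength = stre, hub_score = hub, betweenness = btw,
                       row.names = NULL, stringsAsFactors = FALSE),
    edges = data.frame(from = el[, 1L], to = el[, 2L],
                       edge_betweenness = ebt, stringsAsFactors = FALSE),
    degree_distribution = dd), class = "linkcor_network_stats")
}

# HITS hub scores for an undirected graph: the principal eigenvector of the
# (weighted) adjacency matrix, normalized to max 1. Computed with the dense
# symmetric eigensolver rather than an iterative method so results are
# deterministic even when the top eigenvalue is degenerate (e.g. identical
# disconnected components).
hub_scores <- function(g, w = NULL) {
  A <- igraph::as_adjacency_matrix(
    g, attr = if (!is.null(w)) "weight" else NULL, sparse = FALSE)
  if (nrow(A) == 1L) return(stats::setNames(1, igraph::V(g)$name))
  v <- eigen(A, symmetric = TRUE)$vectors[, 1L]
  v <- abs(v)                      # Perron orientation; magnitudes for ties
  stats::setNames(v / max(v), igraph::V(g)$name)
}

#' @export
print.linkcor_network_stats <- function(x, ...) {
  cat(sprintf("network statistics: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(utils::head(x$nodes[order(-x$nodes$degree), ], 5L), digits = 3)
  invisible(x)
}

#' Community detection on a network view
#'
#' Three algorithm families: greedy modularity optimization
#' (`"greedy_modularity"`), normalized-Laplacian spectral partitioning with
#' the number of clusters chosen by the eigengap heuristic and a seeded
#' k-means step (`"spectral"`), and divisive edge-betweenness clustering
#' (`"edge_betweenness"`). Edge weights are treated as affinities by the
#' modularity-based and spectral methods; edge-betweenness splits use the
#' unweighted topology. Deterministic given `seed`.
#'
#' @param g undirected igraph graph.
#' @param method one of `"greedy_modularity"`, `"spectral"`,
#'   `"edge_betweenness"`.
#' @param seed integer seed for the spectral k-means step.
#' @param kmax largest cluster count considered by the eigengap heuristic.
#' @return object of class `linkcor_communities`: list with named integer
#'   `membership`, `modularity`, `method` and `n_communities`.
#' @export
detect_communities <- function(g, method = c("greedy_modularity", "spectral",
                                             "edge_betweenness"),
                               seed = 1L, kmax = 10L) {
  method <- match.arg(method)
  stopifnot(igraph::is_igraph(g))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_along(nm), nm)
    return(new_communities(memb, 0, method))
  }
  memb <- switch(method,
    greedy_modularity = {
      cl <- igraph::cluster_fast_greedy(g, weights = w)
      stats::setNames(as.integer(igraph::membership(cl)), nm)
    },
    edge_betweenness = {
      cl <- igraph::cluster_edge_betweenness(g, weights = NA)
      stats::setNames(as.integer(igraph::membership(cl)), nm)
    },
    spectral = spectral_membership(g, seed = seed, kmax = kmax))
  mod <- igraph::modularity(g, memb, weights = w)
  new_communities(memb, mod, method)
}

new_communities <- function(membership, modularity, method) {
  structure(list(membership = membership, modularity = modularity,
                 method = method,
                 n_communities = length(unique(membership))),
            class = "linkcor_communities")
}

#' @export
print.linkcor_communities <- function(x, ...) {
  cat(sprintf("communities (%s): %d communities, modularity %.4f\n",
              x$method, x$n_communities, x$modularity))
  invisible(x)
}

# normalized-Laplacian spectral partitioning, eigengap-selected k,
# seed-controlled kmeans on the row-normalized eigenvector embedding
spectral_membership <- function(g, seed = 1L, kmax = 10L) {
  nm <- igraph::V(g)$name
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
    igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE)
  d <- rowSums(A)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  Lsym <- diag(n) - (dis %o% dis) * A
  ev <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(ev$values)                      # ascending
  vecs <- ev$vectors[, n:1, drop = FALSE]
  kmax <- max(1L, min(kmax, n - 1L))
  gaps <- diff(vals[seq_len(kmax + 1L)])
  k <- which.max(gaps)
  if (k <= 1L) return(stats::setNames(rep(1L, n), nm))
  U <- vecs[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  old <- if (exists(".Random.seed", envir = globalenv())) {
    s <- get(".Random.seed", envir = globalenv()); s
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 20L)
  stats::setNames(as.integer(km$cluster), nm)
}

#' Plot the integrated network
#'
#' Draws the weighted vertex network (edge width proportional to the number
#' of confounding linkers) or the bipartite linker-vertex view.
#'
#' @param x a `linkcor` object with significant triplets.
#' @param view `"weighted"` or `"bipartite"`.
#' @param seed layout seed.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.linkcor <- function(x, view = c("weighted", "bipartite"), seed = 1L, ...) {
  view <- match.arg(view)
  g <- if (view == "weighted") as_weighted_graph(x) else as_bipartite_graph(x)
  with_seed(seed, {
    lay <- igraph::layout_with_fr(g)
    if (view == "weighted")
      igraph::plot.igraph(g, layout = lay,
                          edge.width = igraph::E(g)$weight, ...)
    else
      igraph::plot.igraph(g, layout = lay,
                          vertex.color = ifelse(igraph::V(g)$type,
                                                "tomato", "steelblue"), ...)
  })
  invisible(x)
}

#' Export a network view as GraphML
#'
#' GraphML preserves node and edge attributes, so the weighted and bipartite
#' views round-trip through standard graph tooling.
#'
#' @param g igraph graph.
#' @param path output file path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
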