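triplet_rows <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  n <- nrow(d)
  cbind(d, r = rep(0.5, n), r_partial = rep(0.1, n),
        delta = rep(0.4, n), sign = rep("weakens", n), z = rep(5, n),
        p_raw = rep(1e-6, n), p_adj = rep(1e-5, n),
        significant = rep(TRUE, n))
}

test_that("weighted graph collapses triplets into confounder-count edges", {
  tt <- triplet_rows(vertex_a = c("a", "a"), vertex_b = c("b", "b"),
                     linker = c("l1", "l2"))
  g <- as_weighted_graph(tt)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2, ignore_attr = TRUE)
  expect_identical(igraph::E(g)$linkers, "l1,l2")

  tt2 <- triplet_rows(vertex_a = c("a", "b"), vertex_b = c("b", "c"),
                      linker = c("l1", "l1"))
  g2 <- as_weighted_graph(tt2)
  expect_equal(igraph::ecount(g2), 2)
  expect_equal(igraph::E(g2)$weight, c(1, 1), ignore_attr = TRUE)
})

test_that("edge weights, linker degrees and incidence sums agree across views", {
  tab <- random_triplet_table(seed = 41)
  g <- as_weighted_graph(tab)
  bg <- as_bipartite_graph(tab)
  inc <- incidence_matrix(tab)

  # edge weight oracle: group-by count of distinct linkers per pair
  key <- paste(tab$vertex_a, tab$vertex_b)
  orc_w <- vapply(split(tab$linker, key), function(x) length(unique(x)), 1L)
  el <- igraph::as_edgelist(g)
  got_w <- igraph::E(g)$weight
  names(got_w) <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_equal(got_w[names(orc_w)], as.numeric(orc_w)[seq_along(orc_w)],
               ignore_attr = TRUE)

  # total weight equals the number of distinct (pair, linker) triplets
  expect_equal(sum(igraph::E(g)$weight), nrow(tab), ignore_attr = TRUE)

  # per-linker: bipartite degree == incidence column sum == distinct vertices
  orc_v <- vapply(split(c(tab$vertex_a, tab$vertex_b), c(tab$linker, tab$linker)),
                  function(x) length(unique(x)), 1L)
  for (l in names(orc_v)) {
    expect_equal(unname(igraph::degree(bg, l)), unname(orc_v[l]), ignore_attr = TRUE)
    expect_equal(sum(inc[, l]), unname(orc_v[l]), ignore_attr = TRUE)
  }
  expect_true(all(colSums(inc) >= 2))
})

test_that("bipartite view has no within-class edges and projects correctly", {
  tt <- triplet_rows(vertex_a = c("a", "a"), vertex_b = c("b", "c"),
                     linker = c("l", "l"))
  bg <- as_bipartite_graph(tt)
  el <- igraph::as_edgelist(bg)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("a l", "b l", "c l"))
  expect_equal(sum(igraph::V(bg)$type), 1)   # one linker node

  tab <- random_triplet_table(seed = 42)
  bg2 <- as_bipartite_graph(tab)
  proj <- igraph::bipartite_projection(bg2)$proj1   # vertex-side projection
  pel <- igraph::as_edgelist(proj)
  got <- sort(paste(pmin(pel[, 1], pel[, 2]), pmax(pel[, 1], pel[, 2])))
  # oracle: a-b linked iff some linker touches both
  inc <- incidence_matrix(tab)
  vs <- rownames(inc)
  orc <- character()
  for (i in seq_along(vs)[-length(vs)]) for (j in seq((i + 1), length(vs))) {
    if (any(inc[i, ] == 1 & inc[j, ] == 1))
      orc <- c(orc, paste(vs[i], vs[j]))
  }
  expect_identical(got, sort(orc))
})

test_that("incidence matrix encodes the hypergraph exactly", {
  tt <- triplet_rows(vertex_a = "a", vertex_b = "b", linker = "l")
  inc <- incidence_matrix(tt)
  expect_identical(dim(inc), c(2L, 1L))
  expect_true(all(inc == 1L))

  tt2 <- triplet_rows(vertex_a = c("a", "c"), vertex_b = c("b", "d"),
                      linker = c("l1", "l2"))
  inc2 <- incidence_matrix(tt2)
  expect_identical(dim(inc2), c(4L, 2L))
  expect_identical(sum(inc2), 4L)
  expect_identical(inc2[c("a", "b"), "l1"], c(a = 1L, b = 1L))
  expect_identical(inc2[c("c", "d"), "l1"], c(c = 0L, d = 0L))
})

test_that("the significant triplet set reconstructs from the weighted view", {
  tab <- random_triplet_table(seed = 43)
  g <- as_weighted_graph(tab)
  el <- igraph::as_edgelist(g)
  rebuilt <- do.call(rbind, lapply(seq_len(nrow(el)), function(e) {
    ls <- strsplit(igraph::E(g)$linkers[e], ",")[[1]]
    data.frame(vertex_a = pmin(el[e, 1], el[e, 2]),
               vertex_b = pmax(el[e, 1], el[e, 2]), linker = ls)
  }))
  expect_setequal(paste(rebuilt$vertex_a, rebuilt$vertex_b, rebuilt$linker),
                  paste(tab$vertex_a, tab$vertex_b, tab$linker))
})

test_that("network statistics match closed forms and brute-force oracles", {
  # path graph a-b-c: the center carries the single indirect pair
  p3 <- triplet_rows(vertex_a = c("a", "b"), vertex_b = c("b", "c"),
                     linker = c("l1", "l1"))
  st <- network_statistics(as_weighted_graph(p3))
  btw <- setNames(st$nodes$betweenness, st$nodes$node)
  expect_identical(btw[["b"]], 1)
  expect_identical(btw[["a"]], 0)
  expect_identical(btw[["c"]], 0)

  # star K_{1,3}
  star <- triplet_rows(vertex_a = c("hub", "hub", "hub"),
                       vertex_b = c("x", "y", "z"),
                       linker = c("l1", "l1", "l1"))
  stn <- network_statistics(as_weighted_graph(star))
  deg <- setNames(stn$nodes$degree, stn$nodes$node)
  expect_identical(deg[["hub"]], 3)
  expect_identical(deg[["x"]], 1)
  btw2 <- setNames(stn$nodes$betweenness, stn$nodes$node)
  expect_identical(btw2[["hub"]], 3)   # pairs (x,y),(x,z),(y,z)

  # 10-node random weighted graph against the brute-force oracles
  set.seed(44)
  n <- 10
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < 0.4) A[i, j] <- A[j, i] <- sample(1:3, 1)
  }
  A[1, 2] <- A[2, 1] <- 1   # keep at least one edge
  nm <- paste0("n", 1:n)
  dimnames(A) <- list(nm, nm)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  st3 <- network_statistics(g)
  idx <- match(st3$nodes$node, nm)
  expect_equal(st3$nodes$degree, rowSums(A > 0)[idx], ignore_attr = TRUE)
  expect_equal(st3$nodes$hub_score, oracle_hub_score(A)[idx],
               tolerance = 1e-6, ignore_attr = TRUE)
  A01 <- (A > 0) + 0
  expect_equal(st3$nodes$betweenness, oracle_betweenness(A01)[idx],
               tolerance = 1e-10, ignore_attr = TRUE)
  el <- igraph::as_edgelist(g)
  eidx <- cbind(match(el[, 1], nm), match(el[, 2], nm))
  expect_equal(st3$edges$edge_betweenness, oracle_edge_betweenness(A01, eidx),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_equal(sum(st3$degree_distribution$n_nodes), n)
})

test_that("community detection recovers planted structure", {
  # two 4-cliques joined by one bridge
  ed <- c()
  for (i in 1:3) for (j in (i + 1):4) ed <- c(ed, i, j, i + 4, j + 4)
  g <- igraph::make_graph(c(ed, 1, 5), directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  truth <- rep(1:2, each = 4)
  for (meth in c("greedy_modularity", "edge_betweenness", "spectral")) {
    cm <- detect_communities(g, meth, seed = 7)
    expect_identical(cm$n_communities, 2L)
    # same partition up to label switching
    expect_identical(length(unique(paste(cm$membership, truth))), 2L)
  }

  # single clique collapses to one community
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("c", 1:4)
  expect_identical(detect_communities(k4, "edge_betweenness")$n_communities, 1L)
  expect_identical(detect_communities(k4, "spectral")$n_communities, 1L)

  # empty edge set: every node its own community
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("i", 1:5)
  cm0 <- detect_communities(g0, "spectral")
  expect_identical(cm0$n_communities, 5L)

  # spectral is deterministic given the seed
  cma <- detect_communities(g, "spectral", seed = 11)
  cmb <- detect_communities(g, "spectral", seed = 11)
  expect_identical(cma$membership, cmb$membership)

  expect_error(detect_communities(g, "louvain"), "arg")
})
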