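# Independent brute-force oracles used across the suite. Everything here is
# written from first principles (sum formulas, path enumeration, power
# iteration, exact combinatorics) so it shares no code path with the package.

# bare numeric values of an omics_matrix, for equality comparisons
as_vals <- function(x) {
  y <- unclass(x)
  attr(y, "role") <- NULL
  attr(y, "dropped") <- NULL
  y
}

# textbook sum-formula Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# partial correlation as the correlation of least-squares residuals on z
oracle_partial_resid <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# multivariate normal sampler via Cholesky (avoids depending on MASS)
rmvn <- function(n, R) {
  p <- ncol(R)
  matrix(stats::rnorm(n * p), n, p) %*% chol(R)
}

# all shortest paths between s and t in an unweighted graph given as a
# 0/1 adjacency matrix; returns list of node-index vectors
oracle_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  best <- Inf
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) - 1L > best) return()
    if (v == t) {
      len <- length(path) - 1L
      if (len < best) { best <<- len; paths <<- list(path) }
      else if (len == best) paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in which(A[v, ] > 0)) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  paths
}

# unnormalized betweenness (pairs counted once) per node, from path counting
oracle_betweenness <- function(A) {
  n <- nrow(A)
  b <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    sp <- oracle_shortest_paths(A, s, t)
    if (!length(sp)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p) v %in% p, TRUE))
      b[v] <- b[v] + through / length(sp)
    }
  }
  b
}

# edge betweenness for the edge list given as a 2-column index matrix
oracle_edge_betweenness <- function(A, edges) {
  n <- nrow(A)
  eb <- numeric(nrow(edges))
  uses_edge <- function(p, a, b) {
    for (i in seq_len(length(p) - 1L))
      if ((p[i] == a && p[i + 1L] == b) || (p[i] == b && p[i + 1L] == a))
        return(TRUE)
    FALSE
  }
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    sp <- oracle_shortest_paths(A, s, t)
    if (!length(sp)) next
    for (e in seq_len(nrow(edges))) {
      cnt <- sum(vapply(sp, uses_edge, TRUE, edges[e, 1L], edges[e, 2L]))
      eb[e] <- eb[e] + cnt / length(sp)
    }
  }
  eb
}

# HITS hub score of an undirected weighted graph: power iteration on A A^T,
# normalized to max 1
oracle_hub_score <- function(A, iters = 5000L) {
  v <- rep(1, nrow(A))
  M <- A %*% t(A)
  for (i in seq_len(iters)) {
    v2 <- as.numeric(M %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
    v <- v2
  }
  v / max(v)
}

# exact upper-tail hypergeometric by enumeration of the sum
oracle_hyper_upper <- function(k, n_in, N, K) {
  j <- seq(k, min(K, n_in))
  sum(choose(n_in, j) * choose(N - n_in, K - j)) / choose(N, K)
}

# random well-formed significant-triplet table for graph/compare tests
random_triplet_table <- function(seed, n_vertex = 8L, n_linker = 4L,
                                 n_rows = 25L) {
  set.seed(seed)
  vs <- paste0("V", seq_len(n_vertex))
  ls <- paste0("L", seq_len(n_linker))
  a <- sample(vs, n_rows, replace = TRUE)
  b <- sample(vs, n_rows, replace = TRUE)
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  d <- data.frame(vertex_a = a2, vertex_b = b2,
                  linker = sample(ls, sum(keep), replace = TRUE),
                  stringsAsFactors = FALSE)
  d <- d[!duplicated(paste(d$vertex_a, d$vertex_b, d$linker)), , drop = FALSE]
  n <- nrow(d)
  d$r <- runif(n, -0.9, 0.9)
  d$r_partial <- runif(n, -0.9, 0.9)
  d$delta <- abs(d$r_partial - d$r)
  d$sign <- ifelse(abs(d$r_partial) > abs(d$r), "strengthens", "weakens")
  d$z <- rnorm(n)
  d$p_raw <- runif(n, 0, 1e-3)
  d$p_adj <- pmin(1, d$p_raw * 2)
  d$significant <- TRUE
  rownames(d) <- NULL
  d
}

# features x samples matrix of pure noise wrapped as an omics_matrix
noise_omics <- function(m, n, seed, role = "vertex", prefix = "F") {
  set.seed(seed)
  mat <- matrix(rnorm(m * n), m, n,
                dimnames = list(paste0(prefix, seq_len(m)),
                                paste0("S", seq_len(n))))
  omics_matrix(mat, role = role)
}

# vertex matrix whose rows have exactly zero pairwise sample correlation
# (each row residualized on all previous rows and the intercept)
orthogonal_omics <- function(m, n, seed, prefix = "V") {
  set.seed(seed)
  rows <- matrix(rnorm(m * n), m, n)
  for (i in seq_len(m)) {
    if (i > 1L) {
      fit <- stats::lm(rows[i, ] ~ t(rows[seq_len(i - 1L), , drop = FALSE]))
      rows[i, ] <- stats::residuals(fit)
    } else {
      rows[i, ] <- rows[i, ] - mean(rows[i, ])
    }
  }
  dimnames(rows) <- list(paste0(prefix, seq_len(m)), paste0("S", seq_len(n)))
  omics_matrix(rows, role = "vertex")
}
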