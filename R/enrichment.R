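#' Local controlling features: linkers enriched in a community
#'
#' A "local controlling feature" is a linker whose significant triplets
#' concentrate in one community of the vertex network, i.e. a confounder
#' that acts on a specific subnetwork of correlated vertices. The enrichment
#' unit is the triplet: a triplet lies inside a community when both of its
#' vertices belong to it; triplets spanning two communities count toward the
#' total `N` but toward no community. For every (linker, community) with at
#' least one inside triplet, a one-sided hypergeometric test asks whether
#' the linker's `K_l` triplets hit the community's `n_in` triplets more
#' often than chance among all `N` significant triplets; p-values are
#' BH-adjusted across all tested (linker, community) pairs.
#'
#' @param x `linkcor` object or triplet data.frame.
#' @param communities a `linkcor_communities` object from
#'   [detect_communities()], or a named membership vector over the vertex
#'   nodes of the network.
#' @param alpha significance level on adjusted p-values.
#' @return data.frame with one row per tested (linker, community):
#'   `linker`, `community`, `k_in`, `K_l`, `n_in`, `N`, `p_raw`, `p_adj`,
#'   `enriched`.
#' @export
local_controlling_features <- function(x, communities, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)")
  tt <- sig_table(x)
  memb <- if (inherits(communities, "linkcor_communities"))
    communities$membership else communities
  if (is.null(names(memb))) stop("'communities' must be a named membership vector")
  nodes <- unique(c(tt$vertex_a, tt$vertex_b))
  miss <- setdiff(nodes, names(memb))
  if (length(miss))
    stop("partition misses vertex node(s): ", paste(miss, collapse = ", "))

  N <- nrow(tt)
  ca <- memb[tt$vertex_a]
  cb <- memb[tt$vertex_b]
  inside <- ca == cb
  comm <- ifelse(inside, ca, NA)
  n_in_tab <- table(comm[inside])
  K_tab <- table(tt$linker)

  cand <- unique(data.frame(linker = tt$linker[inside],
                            community = as.character(comm[inside]),
                            stringsAsFactors = FALSE))
  if (nrow(cand) == 0L)
    return(data.frame(linker = character(), community = character(),
                      k_in = integer(), K_l = integer(), n_in = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  key_all <- paste(tt$linker, comm, sep = "\r")
  k_tab <- table(key_all[inside])
  cand$k_in <- as.integer(k_tab[paste(cand$linker, cand$community, sep = "\r")])
  cand$K_l <- as.integer(K_tab[cand$linker])
  cand$n_in <- as.integer(n_in_tab[cand$community])
  cand$N <- N
  # upper tail: P(X >= k_in) drawing K_l triplets from N with n_in "inside"
  cand$p_raw <- stats::phyper(cand$k_in - 1L, cand$n_in, N - cand$n_in,
                              cand$K_l, lower.tail = FALSE)
  cand$p_adj <- stats::p.adjust(cand$p_raw, method = "BH")
  cand$enriched <- cand$p_adj < alpha
  cand <- cand[order(cand$p_adj, cand$linker, cand$community), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
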