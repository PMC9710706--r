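#' Pairwise feature correlations with significance
#'
#' Correlates every unordered pair of features (rows) over the samples
#' (columns). Two-sided p-values come from the t distribution with n-2
#' degrees of freedom; Benjamini-Hochberg adjustment is applied across all
#' pairs jointly.
#'
#' @param x matrix or [omics_matrix] (features x samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `cor_test`: list with symmetric matrices `r`,
#'   `p_raw`, `p_adj` (diagonal `NA` in the p matrices), sample count `n`
#'   and `method`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_bare_matrix(x)
  n <- ncol(m)
  if (n < 4L) stop("at least 4 samples required, got ", n)
  vars <- apply(m, 1L, stats::var)
  if (any(vars == 0))
    stop("constant feature(s): ", paste(rownames(m)[vars == 0], collapse = ", "))
  r <- stats::cor(t(m), method = method)
  p <- cor_pvalue(r, n)
  diag(p) <- NA_real_
  padj <- p
  ut <- upper.tri(p)
  padj[ut] <- stats::p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(r = r, p_raw = p, p_adj = padj, n = n, method = method),
            class = "cor_test")
}

# two-sided p for a correlation via t with n-2 df
cor_pvalue <- function(r, n) {
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' @export
print.cor_test <- function(x, ...) {
  cat(sprintf("cor_test: %d features, n = %d samples, method = %s\n",
              nrow(x$r), x$n, x$method))
  invisible(x)
}

#' Significantly correlated feature pairs
#'
#' Sparsification step: selects the unordered pairs whose (adjusted)
#' correlation p-value falls below `alpha`. Pairs are returned in
#' deterministic lexicographic order.
#'
#' @param corr a `cor_test` from [correlation_matrix()].
#' @param alpha significance level in (0, 1); `alpha = 1` is the vacuous
#'   threshold returning every pair.
#' @param use_adjusted threshold the BH-adjusted p-values (default) or the
#'   raw ones.
#' @return data.frame with columns `feature_a`, `feature_b` (`feature_a <
#'   feature_b`), `r`, `p_raw`, `p_adj`.
#' @export
significant_pairs <- function(corr, alpha = 0.05, use_adjusted = TRUE) {
  stopifnot(inherits(corr, "cor_test"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single number in (0, 1]")
  if (alpha == 1) return(all_pairs(corr))
  ids <- rownames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  p_use <- if (use_adjusted) corr$p_adj[idx] else corr$p_raw[idx]
  keep <- p_use < alpha
  out <- data.frame(feature_a = a[keep], feature_b = b[keep],
                    r = corr$r[idx][keep],
                    p_raw = corr$p_raw[idx][keep],
                    p_adj = corr$p_adj[idx][keep],
                    stringsAsFactors = FALSE)
  out[order(out$feature_a, out$feature_b), , drop = FALSE]
}

# every unordered pair, same columns as significant_pairs()
all_pairs <- function(corr) {
  ids <- rownames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(feature_a = a, feature_b = b, r = corr$r[idx],
                    p_raw = corr$p_raw[idx], p_adj = corr$p_adj[idx],
                    stringsAsFactors = FALSE)
  out[order(out$feature_a, out$feature_b), , drop = FALSE]
}

#' First-order partial correlation from three pairwise correlations
#'
#' Correlation between x and y after removing the linear effect of a single
#' control variable z:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}}
#' It equals the Pearson correlation of the least-squares residuals of x and
#' y on z.
#'
#' @param r_xy,r_xz,r_yz pairwise correlation coefficients.
#' @return partial correlation coefficient(s); vectorized.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1))
    stop("degenerate control: |r_xz| and |r_yz| must be < 1 (control variable collinear with a vertex feature)")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

clamp_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

# Steiger (1980) Z for two dependent, non-overlapping correlations r12 vs r34,
# with the Pearson-Filon covariance evaluated at the pooled coefficient.
# All arguments vectorized; returns list(z, p).
steiger_z_dependent <- function(r12, r34, r13, r14, r23, r24, n) {
  z1 <- atanh(clamp_r(r12))
  z2 <- atanh(clamp_r(r34))
  rb <- clamp_r((r12 + r34) / 2)
  psi <- 0.5 * rb^2 * (r13^2 + r14^2 + r23^2 + r24^2) + r13 * r24 + r14 * r23 -
    rb * (r13 * r14 + r23 * r24 + r13 * r23 + r14 * r24)
  cc <- psi / (1 - rb^2)^2
  cc <- pmin(pmax(cc, -1), 1 - 1e-12)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cc))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Closed-form correlations among {x, y, x*, y*} (x*, y* the residuals of x, y
# on z) expressed in the three pairwise sample correlations; feeds the Steiger
# comparison of r(x,y) with the partial correlation r(x,y|z).
steiger_from_correlations <- function(r_xy, r_xz, r_yz, n) {
  r_xz <- clamp_r(r_xz); r_yz <- clamp_r(r_yz)
  sx <- sqrt(1 - r_xz^2)
  sy <- sqrt(1 - r_yz^2)
  num <- r_xy - r_xz * r_yz
  r_p <- num / (sx * sy)        # cor(x*, y*) = partial correlation
  r13 <- sx                     # cor(x, x*)
  r24 <- sy                     # cor(y, y*)
  r14 <- num / sy               # cor(x, y*)
  r23 <- num / sx               # cor(y, x*)
  st <- steiger_z_dependent(r_xy, r_p, r13, r14, r23, r24, n)
  list(r = r_xy, r_partial = r_p, delta = abs(r_p - r_xy), z = st$z, p = st$p)
}

#' Test whether conditioning on z changes the correlation of x and y
#'
#' Compares the zero-order correlation r(x, y) with the first-order partial
#' correlation r(x, y | z) on the same sample. The partial correlation is
#' realized as the correlation of the least-squares residuals x* and y* of x
#' and y on z, and the two coefficients are compared with Steiger's (1980) Z
#' for dependent, non-overlapping correlations: both are Fisher-transformed,
#' and their covariance is estimated by the Pearson-Filon expression in the
#' six pairwise correlations among x, y, x*, y*, evaluated at the pooled
#' coefficient; n - 3 effective degrees of freedom are used for both terms.
#' A significant result marks z as a putative confounder of the x-y
#' relationship.
#'
#' Because both coefficients are estimated from the same sample, the test is
#' conservative when z is (nearly) unrelated to x and y: the null p-values
#' concentrate near 1 rather than being uniform, so the screen's realized
#' false-positive rate is far below nominal.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4), non-constant.
#' @return object of class `steiger_test`: list with `r`, `r_partial`,
#'   `delta` (`|r_partial - r|`), statistic `z`, two-sided `p`, and `n`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50, sd = 0.5); y <- z + rnorm(50, sd = 0.5)
#' steiger_test(x, y, z)
#' @export
steiger_test <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4L) stop("at least 4 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("constant input vector")
  res <- steiger_from_correlations(stats::cor(x, y), stats::cor(x, z),
                                   stats::cor(y, z), n)
  structure(c(res, list(n = n)), class = "steiger_test")
}

#' @export
print.steiger_test <- function(x, ...) {
  cat(sprintf("Steiger test of r vs r|z (n = %d)\n", x$n))
  cat(sprintf("  r = %.4f, r|z = %.4f, |delta| = %.4f\n", x$r, x$r_partial, x$delta))
  cat(sprintf("  Z = %.4f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}
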