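#' Seeded latent-factor simulator for paired omics datasets
#'
#' Generates a linker and a vertex matrix over the same samples from a
#' low-rank factor model: each view draws its own `k_factors` standard
#' normal factor scores (n x k) and sparse loadings (every feature-factor
#' loading is active with probability `activation_prob` and then standard
#' normal), and `data = loadings %*% t(scores) + noise` with i.i.d.
#' Gaussian noise. Factors are view-specific, giving each view the
#' correlated-feature structure real omics data shows while keeping the two
#' views independent at baseline — so every cross-view confounding
#' relationship in a benchmark dataset is one deliberately added by
#' [induce_true_triplets()], and recovery rates are well defined. (With
#' factors shared across views, every linker loading on a factor that
#' drives a correlated vertex pair would be a genuine confounder, and no
#' induced-triplet ground truth could label it.)
#'
#' @param n_samples,p_linker,m_vertex,k_factors dimensions.
#' @param noise_sd standard deviation of the additive noise.
#' @param activation_prob probability a feature loads on a factor.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @return list with `linker` and `vertex` ([omics_matrix] objects, features
#'   `L1..Lp` / `V1..Vm`, samples `S1..Sn`) and the `loadings` used.
#' @export
simulate_latent_datasets <- function(n_samples = 100L, p_linker = 20L,
                                     m_vertex = 30L, k_factors = 3L,
                                     noise_sd = 1, activation_prob = 0.5,
                                     seed = 1L) {
  stopifnot(n_samples >= 4L, p_linker >= 1L, m_vertex >= 2L, k_factors >= 1L,
            noise_sd >= 0, activation_prob > 0, activation_prob <= 1)
  with_seed(seed, {
    Zl <- matrix(stats::rnorm(n_samples * k_factors), n_samples, k_factors)
    Zv <- matrix(stats::rnorm(n_samples * k_factors), n_samples, k_factors)
    Wl <- matrix(stats::rnorm(p_linker * k_factors), p_linker, k_factors) *
      (matrix(stats::runif(p_linker * k_factors), p_linker, k_factors) < activation_prob)
    Wv <- matrix(stats::rnorm(m_vertex * k_factors), m_vertex, k_factors) *
      (matrix(stats::runif(m_vertex * k_factors), m_vertex, k_factors) < activation_prob)
    Lm <- Wl %*% t(Zl) + matrix(stats::rnorm(p_linker * n_samples, sd = noise_sd),
                                p_linker, n_samples)
    Vm <- Wv %*% t(Zv) + matrix(stats::rnorm(m_vertex * n_samples, sd = noise_sd),
                                m_vertex, n_samples)
    dimnames(Lm) <- list(paste0("L", seq_len(p_linker)), paste0("S", seq_len(n_samples)))
    dimnames(Vm) <- list(paste0("V", seq_len(m_vertex)), paste0("S", seq_len(n_samples)))
    list(linker = omics_matrix(Lm, role = "linker"),
         vertex = omics_matrix(Vm, role = "vertex"),
         loadings = list(linker = Wl, vertex = Wv))
  })
}

#' Inject ground-truth confounder triplets
#'
#' Modifies the vertex matrix so that selected disjoint vertex pairs acquire
#' a known confounder among the linker features. For a chosen triplet
#' (a, b, l) the standardized linker profile is added as a common cause,
#' `a' = a + beta * l~` and `b' = b + s * beta * l~`, where the sign pattern
#' `s` is +1 when pushing the pair correlation toward +1 leaves enough
#' headroom (`1 - r_ab >= t`) and -1 (opposite loadings) otherwise. `beta`
#' is found by bisection so the achieved absolute change in the pair
#' correlation lands in `[0.9 t, t]`, honoring the upper bound t on
#' |induced - original| while making t an effective effect size. Pairs where
#' the band cannot be reached within 100 bisection steps are skipped with a
#' warning.
#'
#' @param linker,vertex the simulated matrices (see
#'   [simulate_latent_datasets()]).
#' @param n_true number of true positive triplets to induce.
#' @param t upper bound on the absolute correlation change, in (0, 2).
#' @param seed integer seed for the pair/linker selection.
#' @param mode `"common_cause"` (both vertices modified, default) or
#'   `"single_vertex"` (only the first vertex of each pair receives the
#'   linker component).
#' @return list with the modified `vertex` matrix and `truth`, a data.frame
#'   of induced triplets (canonical `vertex_a < vertex_b`) with the before /
#'   after correlations, achieved change and `beta`.
#' @export
induce_true_triplets <- function(linker, vertex, n_true = 5L, t = 0.4,
                                 seed = 1L,
                                 mode = c("common_cause", "single_vertex")) {
  mode <- match.arg(mode)
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 2)
    stop("'t' must be a single number in (0, 2)")
  V <- as_bare_matrix(vertex)
  L <- as_bare_matrix(linker)
  m <- nrow(V)
  if (n_true < 1L || n_true > floor(m / 2))
    stop("'n_true' must be between 1 and floor(m_vertex / 2) = ", floor(m / 2))
  if (n_true > nrow(L))
    stop("need at least ", n_true, " linker features for distinct linkers")

  with_seed(seed, {
    vperm <- sample(rownames(V))
    n_cand <- floor(m / 2)
    cand_a <- vperm[seq(1L, by = 2L, length.out = n_cand)]
    cand_b <- vperm[seq(2L, by = 2L, length.out = n_cand)]
    linker_pool <- sample(rownames(L))

    truth <- list()
    got <- 0L; li <- 1L; skipped <- 0L
    for (ci in seq_len(n_cand)) {
      if (got >= n_true || li > length(linker_pool)) break
      a <- cand_a[ci]; b <- cand_b[ci]; l <- linker_pool[li]
      lt <- as.numeric(scale(L[l, ]))
      fit <- bisect_injection(V[a, ], V[b, ], lt, t, mode)
      if (is.null(fit)) {
        skipped <- skipped + 1L
        warning(sprintf("could not reach the correlation-change band for pair (%s, %s); skipped",
                        a, b), call. = FALSE)
        next
      }
      V[a, ] <- fit$a; V[b, ] <- fit$b
      got <- got + 1L; li <- li + 1L
      truth[[got]] <- data.frame(
        vertex_a = min(a, b), vertex_b = max(a, b), linker = l,
        r_before = fit$r_before, r_after = fit$r_after,
        achieved_delta = abs(fit$r_after - fit$r_before),
        beta = fit$beta, sign_pattern = fit$s, stringsAsFactors = FALSE)
    }
    truth <- if (got) do.call(rbind, truth) else
      data.frame(vertex_a = character(), vertex_b = character(),
                 linker = character(), r_before = numeric(),
                 r_after = numeric(), achieved_delta = numeric(),
                 beta = numeric(), sign_pattern = numeric(),
                 stringsAsFactors = FALSE)
    if (got < n_true)
      warning(sprintf("induced %d of %d requested triplets (%d pair(s) skipped)",
                      got, n_true, skipped), call. = FALSE)
    list(vertex = omics_matrix(V, role = "vertex"), truth = truth)
  })
}

# find beta so that |cor(a', b') - cor(a, b)| lands in [0.9 t, t]
bisect_injection <- function(a, b, lt, t, mode) {
  r0 <- stats::cor(a, b)
  s <- if (1 - r0 >= t) 1 else -1
  modb <- if (mode == "single_vertex") 0 else s
  gfun <- function(beta)
    abs(stats::cor(a + beta * lt, b + modb * beta * lt) - r0)
  hi <- 1
  for (i in seq_len(60L)) {
    if (gfun(hi) >= 0.9 * t) break
    hi <- hi * 2
  }
  if (gfun(hi) < 0.9 * t) return(NULL)
  lo <- 0; beta <- NA_real_
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    g <- gfun(mid)
    if (g > t) hi <- mid
    else if (g < 0.9 * t) lo <- mid
    else { beta <- mid; break }
  }
  if (is.na(beta)) return(NULL)
  list(a = a + beta * lt, b = b + modb * beta * lt, beta = beta, s = s,
       r_before = r0, r_after = stats::cor(a + beta * lt, b + modb * beta * lt))
}

triplet_key <- function(d) {
  lo <- pmin(d$vertex_a, d$vertex_b)
  hi <- pmax(d$vertex_a, d$vertex_b)
  paste(lo, hi, d$linker, sep = "\r")
}

#' Score recovery of induced triplets
#'
#' Compares the significant triplets of an integration against the induced
#' ground truth. A true positive is an exact (vertex pair, linker) match.
#' The universe for true negatives is the set of tested triplets. When a
#' truth triplet was never tested (e.g. its linker fell to the variance
#' pre-filter, or its pair to the sparsification), `on_missing = "error"`
#' (default) aborts with the cause, while `"count_as_fn"` counts it as a
#' false negative and extends the universe accordingly — the behavior the
#' benchmark uses, since aggressive pre-filtering is supposed to show up as
#' lost sensitivity.
#'
#' @param fit `linkcor` object or full triplet data.frame (tested universe with
#'   `significant` flags).
#' @param truth data.frame with `vertex_a`, `vertex_b`, `linker` (order of
#'   the pair irrelevant), e.g. from [induce_true_triplets()].
#' @param on_missing what to do with truth triplets absent from the tested
#'   universe.
#' @return one-row data.frame: `tp`, `fp`, `fn`, `tn`, `universe`,
#'   `sensitivity`, `specificity`, `fdr` (0/0 taken as 0),
#'   `recovered_fraction`, `n_truth`, `n_untested_truth`.
#' @export
evaluate_recovery <- function(fit, truth,
                              on_missing = c("error", "count_as_fn")) {
  on_missing <- match.arg(on_missing)
  tab <- if (inherits(fit, "linkcor")) triplets(fit) else fit
  uni_keys <- triplet_key(tab)
  pred_keys <- uni_keys[tab$significant]
  truth_keys <- unique(triplet_key(truth))
  missing <- setdiff(truth_keys, uni_keys)
  if (length(missing) && on_missing == "error")
    stop(length(missing), " truth triplet(s) not in the tested universe ",
         "(filtered before testing, e.g. by the variance pre-filter or pair ",
         "sparsification): ", paste(gsub("\r", "/", missing), collapse = ", "))
  universe <- length(uni_keys) + length(missing)
  tp <- sum(pred_keys %in% truth_keys)
  fp <- length(pred_keys) - tp
  fn <- length(truth_keys) - tp
  tn <- universe - tp - fp - fn
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, universe = universe,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
             recovered_fraction = if (length(truth_keys) > 0)
               tp / length(truth_keys) else NA_real_,
             n_truth = length(truth_keys),
             n_untested_truth = length(missing))
}

#' Default benchmark condition grid
#'
#' Crosses sample size, the high-variance pre-filter switch and the
#' correlation-change bound t, holding the generator at its default
#' dimensions.
#'
#' @param n_samples,fhvf,t factor levels to cross.
#' @param m_vertex,p_linker,k_factors,noise_sd,n_true,fhvf_quantile held
#'   constant across the grid.
#' @return data.frame of simulation configurations for [run_benchmark()].
#' @export
benchmark_grid <- function(n_samples = c(10L, 100L), fhvf = c(FALSE, TRUE),
                           t = c(0.2, 0.4, 0.6), m_vertex = 30L,
                           p_linker = 20L, k_factors = 3L, noise_sd = 1,
                           n_true = 5L, fhvf_quantile = 0.75) {
  g <- expand.grid(n_samples = n_samples, fhvf = fhvf, t = t,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$m_vertex <- m_vertex; g$p_linker <- p_linker; g$k_factors <- k_factors
  g$noise_sd <- noise_sd; g$n_true <- n_true; g$fhvf_quantile <- fhvf_quantile
  g
}

#' Simulation benchmark: sensitivity, specificity, false discovery rate
#'
#' For every configuration row, repeatedly (i) simulates paired datasets,
#' (ii) induces ground-truth confounder triplets, (iii) runs the full
#' integration, and (iv) scores recovery. All randomness derives from
#' `master_seed`, so the whole table is reproducible. Truth triplets that
#' fall out of the tested universe (pre-filtered linkers, non-significant
#' pairs) count as false negatives.
#'
#' @param configs data.frame of configurations, see [benchmark_grid()].
#' @param n_repetitions independent repetitions per configuration.
#' @param master_seed integer; every repetition's seeds are drawn from it.
#' @param alpha_pair,alpha_triplet,sparsify_pairs forwarded to [linkcor()].
#' @return object of class `linkcor_benchmark`: list with per-repetition
#'   `results`, per-configuration `summary` (mean and sd of the rates), the
#'   `configs`, `n_repetitions` and `master_seed`.
#' @export
run_benchmark <- function(configs = benchmark_grid(), n_repetitions = 20L,
                          master_seed = 1L, alpha_pair = 0.05,
                          alpha_triplet = 0.05, sparsify_pairs = TRUE) {
  stopifnot(is.data.frame(configs), n_repetitions >= 1L)
  nc <- nrow(configs)
  seeds <- with_seed(master_seed,
    array(sample.int(.Machine$integer.max - 1L, nc * n_repetitions * 2L),
          dim = c(nc, n_repetitions, 2L)))
  rows <- vector("list", nc * n_repetitions)
  idx <- 0L
  for (ci in seq_len(nc)) {
    cf <- configs[ci, ]
    for (rep_i in seq_len(n_repetitions)) {
      sim <- simulate_latent_datasets(
        n_samples = cf$n_samples, p_linker = cf$p_linker,
        m_vertex = cf$m_vertex, k_factors = cf$k_factors,
        noise_sd = cf$noise_sd, seed = seeds[ci, rep_i, 1L])
      ind <- suppressWarnings(induce_true_triplets(
        sim$linker, sim$vertex, n_true = cf$n_true, t = cf$t,
        seed = seeds[ci, rep_i, 2L]))
      fit <- linkcor(ind$vertex, sim$linker,
                  alpha_pair = alpha_pair, alpha_triplet = alpha_triplet,
                  sparsify_pairs = sparsify_pairs,
                  fhvf = cf$fhvf, fhvf_quantile = cf$fhvf_quantile)
      ev <- evaluate_recovery(fit, ind$truth, on_missing = "count_as_fn")
      idx <- idx + 1L
      rows[[idx]] <- cbind(config = ci, rep = rep_i, cf, ev,
                           row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  rates <- c("sensitivity", "specificity", "fdr", "recovered_fraction")
  summ <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    d <- results[results$config == ci, , drop = FALSE]
    out <- cbind(config = ci, configs[ci, ], row.names = NULL)
    for (v in rates) {
      out[[paste0("mean_", v)]] <- mean(d[[v]], na.rm = TRUE)
      out[[paste0("sd_", v)]] <- stats::sd(d[[v]])
    }
    out
  }))
  structure(list(results = results, summary = summ, configs = configs,
                 n_repetitions = n_repetitions, master_seed = master_seed),
            class = "linkcor_benchmark")
}

#' @export
print.linkcor_benchmark <- function(x, ...) {
  cat(sprintf("simulation benchmark: %d configuration(s) x %d repetitions (master seed %d)\n",
              nrow(x$configs), x$n_repetitions, x$master_seed))
  cols <- c("n_samples", "fhvf", "t", "mean_sensitivity", "mean_specificity",
            "mean_fdr", "mean_recovered_fraction")
  print(x$summary[, intersect(cols, names(x$summary))], digits = 3, row.names = FALSE)
  invisible(x)
}
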