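test_that("the generator is seed-deterministic and leaves RNG state alone", {
  s1 <- simulate_latent_datasets(n_samples = 20, p_linker = 5, m_vertex = 6,
                                 seed = 71)
  s2 <- simulate_latent_datasets(n_samples = 20, p_linker = 5, m_vertex = 6,
                                 seed = 71)
  expect_identical(as_vals(s1$linker), as_vals(s2$linker))
  expect_identical(as_vals(s1$vertex), as_vals(s2$vertex))

  s3 <- simulate_latent_datasets(n_samples = 20, p_linker = 5, m_vertex = 6,
                                 seed = 72)
  expect_false(identical(as_vals(s1$vertex), as_vals(s3$vertex)))

  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_latent_datasets(seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("the noiseless rank-1 limit correlates loaded features at |r| = 1", {
  suppressWarnings(
    sim <- simulate_latent_datasets(n_samples = 30, p_linker = 6,
                                    m_vertex = 8, k_factors = 1,
                                    noise_sd = 0, seed = 73))
  V <- as_vals(sim$vertex)   # zero-loading rows were dropped as constant
  expect_gte(nrow(V), 2)
  C <- cor(t(V))
  expect_true(all(abs(abs(C) - 1) < 1e-8))
})

test_that("the sample covariance approaches the factor-model covariance", {
  err <- vapply(c(60L, 400L), function(n) {
    sim <- simulate_latent_datasets(n_samples = n, p_linker = 4,
                                    m_vertex = 12, k_factors = 3,
                                    noise_sd = 1, seed = 74)
    W <- sim$loadings$vertex
    target <- W %*% t(W) + diag(nrow(W))
    S <- cov(t(as_vals(sim$vertex)))
    norm(S - target, "F") / norm(target, "F")
  }, 1.0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.25)
})

test_that("induced triplets hit the target correlation-change band", {
  sim <- simulate_latent_datasets(n_samples = 200, seed = 75)
  for (t in c(0.2, 0.6)) {
    ind <- induce_true_triplets(sim$linker, sim$vertex, n_true = 5, t = t,
                                seed = 76)
    expect_identical(nrow(ind$truth), 5L)
    expect_true(all(ind$truth$achieved_delta >= 0.9 * t - 1e-9))
    expect_true(all(ind$truth$achieved_delta <= t + 1e-9))
    # direct recomputation from the returned matrices
    for (i in seq_len(nrow(ind$truth))) {
      a <- ind$truth$vertex_a[i]; b <- ind$truth$vertex_b[i]
      r_new <- cor(as.numeric(ind$vertex[a, ]), as.numeric(ind$vertex[b, ]))
      r_old <- cor(as.numeric(sim$vertex[a, ]), as.numeric(sim$vertex[b, ]))
      expect_equal(abs(r_new - r_old), ind$truth$achieved_delta[i],
                   tolerance = 1e-12)
    }
    # disjoint pairs, distinct linkers, untouched features unchanged
    vs <- c(ind$truth$vertex_a, ind$truth$vertex_b)
    expect_identical(anyDuplicated(vs), 0L)
    expect_identical(anyDuplicated(ind$truth$linker), 0L)
    untouched <- setdiff(rownames(sim$vertex), vs)
    expect_identical(as_vals(ind$vertex)[untouched, ],
                     as_vals(sim$vertex)[untouched, ])
  }
  expect_error(induce_true_triplets(sim$linker, sim$vertex, t = 0), "'t'")
  expect_error(induce_true_triplets(sim$linker, sim$vertex, n_true = 100),
               "n_true")
})

test_that("with no induced triplets the screen keeps the significant fraction below alpha", {
  fracs <- vapply(1:10, function(i) {
    sim <- simulate_latent_datasets(n_samples = 60, p_linker = 10,
                                    m_vertex = 15, seed = 700 + i)
    fit <- linkcor(sim$vertex, sim$linker)
    if (fit$counts$n_triplets_tested == 0) return(0)
    fit$counts$n_significant / fit$counts$n_triplets_tested
  }, 1.0)
  expect_lte(mean(fracs), 0.05)
})

test_that("recovery scoring matches set algebra and handles edge cases", {
  tab <- random_triplet_table(seed = 77, n_vertex = 10, n_linker = 5,
                              n_rows = 60)
  set.seed(78)
  tab$significant <- runif(nrow(tab)) < 0.4
  truth <- tab[sample(nrow(tab), 8), c("vertex_a", "vertex_b", "linker")]

  ev <- evaluate_recovery(tab, truth)
  keys <- paste(tab$vertex_a, tab$vertex_b, tab$linker)
  pk <- keys[tab$significant]
  tk <- paste(truth$vertex_a, truth$vertex_b, truth$linker)
  tp <- length(intersect(pk, tk)); fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  expect_identical(ev$tp, tp)
  expect_identical(ev$fp, fp)
  expect_identical(ev$fn, fn)
  expect_identical(ev$tn, nrow(tab) - tp - fp - fn)
  expect_equal(ev$sensitivity, tp / (tp + fn))
  expect_equal(ev$specificity, ev$tn / (ev$tn + fp))
  expect_equal(ev$fdr, fp / (fp + tp))

  # perfect prediction
  tab2 <- tab; tab2$significant <- keys %in% tk
  ev2 <- evaluate_recovery(tab2, truth)
  expect_identical(c(ev2$sensitivity, ev2$specificity, ev2$fdr), c(1, 1, 0))

  # no positives at all: fdr defined as 0
  tab3 <- tab; tab3$significant <- FALSE
  ev3 <- evaluate_recovery(tab3, truth)
  expect_identical(c(ev3$sensitivity, ev3$specificity, ev3$fdr), c(0, 1, 0))

  # truth outside the universe errors by default, counts as FN on request
  ghost <- truth; ghost$linker <- "L_missing"
  expect_error(evaluate_recovery(tab, ghost), "not in the tested universe")
  ev4 <- evaluate_recovery(tab, ghost, on_missing = "count_as_fn")
  expect_identical(ev4$fn, length(unique(paste(ghost$vertex_a, ghost$vertex_b,
                                               ghost$linker))))
  expect_identical(ev4$universe, nrow(tab) + ev4$fn)
})

test_that("benchmark bookkeeping: rows, summary, reproducibility", {
  grid <- benchmark_grid(n_samples = 40L, fhvf = FALSE, t = 0.5,
                         m_vertex = 10L, p_linker = 6L, n_true = 2L)
  bm <- run_benchmark(grid, n_repetitions = 3, master_seed = 80)
  expect_identical(nrow(bm$results), 3L)
  expect_identical(nrow(bm$summary), 1L)
  expect_true(all(c("mean_sensitivity", "sd_fdr") %in% names(bm$summary)))
  expect_true(all(bm$results$sensitivity >= 0 & bm$results$sensitivity <= 1))

  bm2 <- run_benchmark(grid, n_repetitions = 3, master_seed = 80)
  expect_identical(bm$results, bm2$results)
})

test_that("aggressive variance filtering drops linkers and costs sensitivity", {
  grid <- benchmark_grid(n_samples = 100L, fhvf = c(FALSE, TRUE), t = 0.6,
                         fhvf_quantile = 0.9)
  bm <- run_benchmark(grid, n_repetitions = 4, master_seed = 81)
  s <- bm$summary
  expect_lte(s$mean_sensitivity[s$fhvf], s$mean_sensitivity[!s$fhvf])
  # filtered runs report untested truth triplets
  expect_gt(sum(bm$results$n_untested_truth[bm$results$fhvf]), 0)
})
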