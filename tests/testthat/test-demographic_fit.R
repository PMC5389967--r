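test_that("composite log-likelihood follows the multinomial arithmetic", {
  # 2x2 spectrum with the two polymorphic entries {3, 1}, probs {.75, .25}
  obs <- matrix(c(0L, 3L, 1L, 0L), 2, 2)
  probs <- matrix(c(0, 0.75, 0.25, 0), 2, 2)
  cl <- composite_log_likelihood(obs, probs)
  expect_equal(cl$log_cl, 3 * log(0.75) + 1 * log(0.25), tolerance = 1e-12)
  expect_equal(cl$n_floored, 0L)

  # information inequality: the truth maximises E[log p] among perturbations
  p_true <- c(0.5, 0.3, 0.2)
  obs2 <- matrix(c(0, 500, 300, 200, 0, 0), 2, 3)  # counts match p_true
  probs_true <- matrix(c(0, p_true, 0, 0), 2, 3)
  cl_true <- composite_log_likelihood(obs2, probs_true)$log_cl
  set.seed(12)
  for (i in 1:10) {
    p_alt <- p_true * exp(rnorm(3, 0, 0.5)); p_alt <- p_alt / sum(p_alt)
    probs_alt <- matrix(c(0, p_alt, 0, 0), 2, 3)
    expect_lt(composite_log_likelihood(obs2, probs_alt)$log_cl, cl_true)
  }

  # zero expected probability at an occupied entry is floored and flagged
  probs0 <- matrix(c(0, 1, 0, 0), 2, 2)
  cl0 <- composite_log_likelihood(obs, probs0, n_sim = 1000)
  expect_equal(cl0$n_floored, 1L)
  expect_equal(cl0$log_cl, 3 * log(1) + 1 * log(1 / 10000),
               tolerance = 1e-12)

  expect_error(composite_log_likelihood(obs, matrix(0.1, 3, 3)), "shape")
})

test_that("fitting is deterministic given the seed", {
  set.seed(61)
  truth <- desk_model()
  obs <- simulate_sfs(truth, 4, 3, 3000)$joint
  bounds <- list(N_anc_all = c(1000, 50000))
  sched <- fit_schedule("desk", cycles = 3, sims_start = 500,
                        sims_end = 1000, replicates = 2)
  set.seed(7)
  f1 <- fit_demography(obs, truth, "N_anc_all", bounds, sched)
  set.seed(7)
  f2 <- fit_demography(obs, truth, "N_anc_all", bounds, sched)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$log_cl, f2$log_cl)
})

test_that("estimates pinned at a search bound are flagged", {
  set.seed(62)
  truth <- desk_model()
  obs <- simulate_sfs(truth, 4, 3, 2000)$joint
  # bounds exclude the truth (8000), forcing a pin at the upper bound
  bounds <- list(N_anc_all = c(100, 1200))
  sched <- fit_schedule("desk", cycles = 3, sims_start = 500,
                        sims_end = 1000, replicates = 1)
  expect_warning(f <- fit_demography(obs, truth, "N_anc_all", bounds,
                                     sched), "bound")
  expect_true(f$at_bound[["N_anc_all"]])
})

test_that("parametric bootstrap produces ordered, covering intervals", {
  set.seed(63)
  truth <- desk_model()
  obs <- simulate_sfs(truth, 4, 3, 4000)$joint
  bounds <- list(N_anc_all = c(1000, 50000))
  sched <- fit_schedule("desk", cycles = 4, sims_start = 500,
                        sims_end = 2000, replicates = 2)
  fit <- fit_demography(obs, truth, "N_anc_all", bounds, sched)
  fit <- parametric_bootstrap_ci(fit, n_datasets = 12,
                                 schedule = fit_schedule(
                                   "desk", cycles = 3, sims_start = 500,
                                   sims_end = 1000, replicates = 1))
  expect_equal(dim(fit$ci95), c(1L, 2L))
  expect_lt(fit$ci95[1, "lo"], fit$ci95[1, "hi"])
  expect_equal(fit$n_failed, 0L)
  # percentile bookkeeping: matches quantile() of the refit estimates
  est <- fit$bootstrap_estimates[, 1L]
  expect_equal(unname(fit$ci95[1, ]),
               unname(stats::quantile(est, c(0.025, 0.975))))
})

test_that("PCA fit check separates self-consistent from alien data", {
  set.seed(64)
  truth <- desk_model()
  ranges <- list(N_anc_all = c(6000, 10000), N_cur_p1 = c(8000, 12000))
  obs_self <- simulate_sfs(truth, 3, 2, 3000)$joint
  chk <- pca_fit_check(obs_self, ranges, truth, n_sims = 120,
                       sites_per_sim = 1500)
  expect_false(chk$degenerate)
  expect_true(chk$inside)

  # observation from a 10x-size model falls outside the cloud
  alien <- im_model(N_cur_p1 = 1e5, N_cur_p2 = 4e4, N_anc_p1 = 1e5,
                    N_anc_p2 = 4e4, N_anc_all = 8e4, T_change_p1 = 0,
                    T_change_p2 = 0, T_split = 20000, m12 = 1e-5,
                    m21 = 1e-5)
  obs_alien <- simulate_sfs(alien, 3, 2, 3000)$joint
  chk2 <- pca_fit_check(obs_alien, ranges, truth, n_sims = 120,
                        sites_per_sim = 1500)
  expect_false(chk2$inside)

  expect_error(pca_fit_check(obs_self, ranges, truth, n_sims = 5),
               "dimensionality")
})
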