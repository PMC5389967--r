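test_that("pairwise coalescence time matches the closed form E[T2] = 2N", {
  set.seed(101)
  N <- 10000
  g <- simulate_site_genealogy(constant_model(N), n1 = 1, n2 = 0,
                               n_reps = 2000)
  # E[T2] = 2N with sd 2N: 2000 reps give s.e. ~ 2N/sqrt(2000)
  se <- 2 * N / sqrt(2000)
  expect_lt(abs(mean(g$tmrca) - 2 * N), 5 * se)
})

test_that("total branch length matches 4N * sum(1/i) for n = 10", {
  set.seed(102)
  N <- 10000
  g <- simulate_site_genealogy(constant_model(N), n1 = 5, n2 = 0,
                               n_reps = 3000)
  expected <- 4 * N * sum(1 / (1:9))
  se <- stats::sd(g$total_length) / sqrt(3000)
  expect_lt(abs(mean(g$total_length) - expected), 5 * se)
})

test_that("with no migration, lineages cannot coalesce before the split", {
  set.seed(103)
  m <- im_model(N_cur_p1 = 1000, N_cur_p2 = 1000, N_anc_p1 = 1000,
                N_anc_p2 = 1000, N_anc_all = 1000, T_change_p1 = 0,
                T_change_p2 = 0, T_split = 50000, m12 = 0, m21 = 0)
  g <- simulate_site_genealogy(m, n1 = 1, n2 = 1, n_reps = 500, ploidy = 1)
  expect_true(all(g$tmrca >= 50000))
})

test_that("Poisson-mutation mode reproduces Watterson's E[S]", {
  set.seed(104)
  n_sites <- 5000
  s <- simulate_sfs(constant_model(10000), n1 = 5, n2 = 0,
                    num_sites = n_sites, mode = "theta_poisson",
                    theta = 1, N_ref = 10000)
  S_per_site <- nrow(s$counts) / n_sites
  expected <- sum(1 / (1:9))             # theta * a1 with theta = 1
  # var(S) per site = theta*a1 + theta^2*a2; s.e. over 5000 sites
  se <- sqrt((expected + sum(1 / (1:9)^2)) / n_sites)
  expect_lt(abs(S_per_site - expected), 2 * se)
})

test_that("fixed-sites mode makes every site polymorphic in the pooled sample", {
  set.seed(105)
  s <- simulate_sfs(constant_model(10000), n1 = 7, n2 = 0,
                    num_sites = 4000)
  k <- s$counts[, "k1"]
  expect_true(all(k >= 1 & k <= 13))
})

test_that("neutral spectra match the theta/k expectation per frequency class", {
  # low theta keeps sites effectively independent, so the multinomial
  # chi-square applies; class probabilities are (1/k)/a1 exactly
  set.seed(109)
  s <- simulate_sfs(constant_model(10000), n1 = 7, n2 = 0,
                    num_sites = 40000, mode = "theta_poisson",
                    theta = 0.1, N_ref = 10000)
  k <- s$counts[, "k1"]
  k <- k[k > 0 & k < 14]
  expect_gt(length(k), 10000)
  probs <- (1 / (1:13)) / sum(1 / (1:13))
  obs <- tabulate(k, nbins = 13L)
  chi <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.01)
})

test_that("a fully symmetric model gives a statistically symmetric joint SFS", {
  set.seed(106)
  m <- im_model(N_cur_p1 = 5000, N_cur_p2 = 5000, N_anc_p1 = 5000,
                N_anc_p2 = 5000, N_anc_all = 5000, T_change_p1 = 1000,
                T_change_p2 = 1000, T_split = 10000, m12 = 1e-4,
                m21 = 1e-4)
  s <- simulate_sfs(m, n1 = 5, n2 = 5, num_sites = 8000)
  # marginal spectra of the two populations drawn from the same law
  c1 <- tabulate(s$counts[, "k1"] + 1L, 11L)
  c2 <- tabulate(s$counts[, "k2"] + 1L, 11L)
  chi <- suppressWarnings(stats::chisq.test(rbind(c1, c2)))
  expect_gt(chi$p.value, 0.01)
})

test_that("deep divergence without migration drives F_ST toward 1", {
  set.seed(107)
  m <- im_model(N_cur_p1 = 1000, N_cur_p2 = 1000, N_anc_p1 = 1000,
                N_anc_p2 = 1000, N_anc_all = 1000, T_change_p1 = 0,
                T_change_p2 = 0, T_split = 2e5, m12 = 0, m21 = 0)
  s <- simulate_sfs(m, n1 = 7, n2 = 6, num_sites = 2000)
  wfst <- {
    d1 <- linepopgen:::dosage_from_counts(s$counts[, "k1"], 7L)
    d2 <- linepopgen:::dosage_from_counts(s$counts[, "k2"], 6L)
    comp <- linepopgen:::wc_components(d1, d2)
    sum(comp$a) / sum(comp$a + comp$b + comp$c)
  }
  expect_gt(wfst, 0.95)
})

test_that("identical seeds reproduce simulations bit for bit", {
  m <- desk_model()
  set.seed(42); a <- simulate_sfs(m, 7, 6, 500)
  set.seed(42); b <- simulate_sfs(m, 7, 6, 500)
  expect_identical(a$counts, b$counts)
  set.seed(42); ga <- simulate_genotypes(m, 3, 3, 50)
  set.seed(42); gb <- simulate_genotypes(m, 3, 3, 50)
  expect_identical(ga$dosage, gb$dosage)
})

test_that("simulated genotypes keep the simulated allele counts", {
  set.seed(108)
  m <- desk_model()
  g <- simulate_genotypes(m, 7, 6, 300)
  expect_true(all(g$dosage %in% 0:2))
  # round-trip through VCF preserves the spectra
  path <- file.path(withr::local_tempdir(), "sim.vcf")
  write_vcf(g, path)
  rt <- read_snp_vcf(path, g$popmap)
  expect_identical(site_sfs(rt, "FLORIDA")$counts,
                   site_sfs(g, "FLORIDA")$counts)
  expect_identical(rt$dosage, g$dosage)
})

test_that("invalid demographic models are rejected before simulation", {
  expect_error(im_model(N_cur_p1 = -1, N_cur_p2 = 1, N_anc_p1 = 1,
                        N_anc_p2 = 1, N_anc_all = 1, T_change_p1 = 0,
                        T_change_p2 = 0, T_split = 1), "sizes")
  expect_error(im_model(N_cur_p1 = 1, N_cur_p2 = 1, N_anc_p1 = 1,
                        N_anc_p2 = 1, N_anc_all = 1, T_change_p1 = 2,
                        T_change_p2 = 0, T_split = 1), "size-change")
  expect_error(im_model(N_cur_p1 = 1, N_cur_p2 = 1, N_anc_p1 = 1,
                        N_anc_p2 = 1, N_anc_all = 1, T_change_p1 = 0,
                        T_change_p2 = 0, T_split = 1, m12 = 2), "migration")
})
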