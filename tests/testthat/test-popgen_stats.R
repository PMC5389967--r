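test_that("site_sfs tallies, folds, and conserves polymorphic counts", {
  # one singleton insertion among 7 Florida diploids
  gt <- make_gt(rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
                n1 = 7, n2 = 6, type = "mei")
  s <- site_sfs(gt, "FLORIDA", "derived")
  expect_equal(s$n, 14L)
  expect_equal(s$counts[2L], 1L)  # k = 1
  expect_equal(sum(s$counts), 1L)

  # folding: derived count 13 of n = 14 lands in folded class 1
  gt2 <- make_gt(rbind(c(2, 2, 2, 2, 2, 2, 1, 0, 0, 0, 0, 0, 0)),
                 n1 = 7, n2 = 6)
  sf <- site_sfs(gt2, "FLORIDA", "minor_folded")
  expect_equal(sf$counts[2L], 1L)

  # explicit dosage list equals a hand tally
  dos <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(2, 2, 2, 1),
               c(0, 0, 0, 0), c(2, 2, 2, 2))
  gt3 <- make_gt(dos, n1 = 4, n2 = 0)
  s3 <- site_sfs(gt3, "FLORIDA", "derived")
  expect_equal(s3$counts, c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(sfs_segregating(s3), 3L)
})

test_that("mean_pairwise_diff matches enumeration of all chromosome pairs", {
  # n = 4 chromosomes, singleton: 3 of 6 pairs differ -> 0.5
  gt <- make_gt(rbind(c(1, 0)), n1 = 2, n2 = 0)
  expect_equal(mean_pairwise_diff(gt, "FLORIDA"), 0.5)
  # n = 2, singleton: the only pair differs
  gt2 <- make_gt(rbind(c(1)), n1 = 1, n2 = 0)
  expect_equal(mean_pairwise_diff(gt2, "FLORIDA"), 1.0)
  # fixed or absent -> 0
  gt3 <- make_gt(rbind(c(0, 0), c(2, 2)), n1 = 2, n2 = 0)
  expect_equal(mean_pairwise_diff(gt3, "FLORIDA"), 0)
  expect_error(mean_pairwise_diff(gt3[integer(0)], "FLORIDA"), "empty")

  # oracle equivalence on random fixtures up to 20 chromosomes x 100 loci
  set.seed(11)
  for (n_dip in c(3L, 7L, 10L)) {
    k <- sample(0:(2L * n_dip), 100L, replace = TRUE)
    dos <- t(vapply(k, function(ki) {
      hap <- c(rep(1L, ki), rep(0L, 2L * n_dip - ki))[sample(2L * n_dip)]
      hap[seq_len(n_dip) * 2L - 1L] + hap[seq_len(n_dip) * 2L]
    }, integer(n_dip)))
    gt <- make_gt(dos, n1 = n_dip, n2 = 0)
    expect_equal(mean_pairwise_diff(gt, "FLORIDA"),
                 oracle_pi(k, 2L * n_dip), tolerance = 1e-12)
  }
})

test_that("tajimas_d reproduces the published constant formulas", {
  # n = 14, one singleton: compare against the independently coded oracle
  gt <- make_gt(rbind(c(1, 0, 0, 0, 0, 0, 0)), n1 = 7, n2 = 0)
  d <- tajimas_d(gt, "FLORIDA")
  expect_lt(d$D, 0)
  expect_equal(d$D, oracle_tajima_d(1L, 14L), tolerance = 1e-12)
  expect_equal(d$a1, sum(1 / 1:13), tolerance = 1e-12)

  # a spectrum at the neutral expectation theta / k gives D near 0
  n <- 14L
  k_classes <- rep(1:(n - 1), times = round(2000 / 1:(n - 1)))
  expect_lt(abs(oracle_tajima_d(k_classes, n)), 0.05)
  dos <- t(vapply(k_classes, function(ki) {
    hap <- c(rep(1L, ki), rep(0L, n - ki))
    hap[seq(1, n, 2)] + hap[seq(2, n, 2)]
  }, integer(7)))
  gt2 <- make_gt(dos, n1 = 7, n2 = 0)
  expect_equal(tajimas_d(gt2, "FLORIDA")$D, oracle_tajima_d(k_classes, n),
               tolerance = 1e-12)

  # no segregating sites is an error, not zero
  gt3 <- make_gt(rbind(c(2, 2, 2, 2, 2, 2, 2)), n1 = 7, n2 = 0)
  expect_error(tajimas_d(gt3, "FLORIDA"), "segregating")
})

test_that("weir_cockerham_fst follows the variance-component algebra", {
  # fixed difference: per-site estimate exactly 1
  gt <- make_gt(rbind(c(2, 2, 2, 0, 0, 0)), n1 = 3, n2 = 3)
  fst <- weir_cockerham_fst(gt)
  expect_equal(fst$per_site, 1)
  expect_equal(fst$weighted_fst, 1)

  # equal frequencies 0.5 in equal samples: small (here negative) estimate
  gt2 <- make_gt(rbind(c(0, 1, 1, 2, 0, 1, 1, 2)), n1 = 4, n2 = 4)
  fst2 <- weir_cockerham_fst(gt2)
  expect_lt(fst2$per_site, 0.05)

  # monomorphic site excluded from the mean, not propagated as NaN
  gt3 <- make_gt(rbind(c(2, 2, 2, 0, 0, 0), c(0, 0, 0, 0, 0, 0)),
                 n1 = 3, n2 = 3)
  fst3 <- weir_cockerham_fst(gt3)
  expect_equal(sum(is.na(fst3$per_site)), 1L)
  expect_equal(fst3$mean_fst, 1)

  expect_error(weir_cockerham_fst(make_gt(rbind(c(1, 0, 0)), n1 = 3,
                                          n2 = 0)), "two populations")
})

test_that("sharing_partition classifies and percentages sum to 100", {
  # private to Florida
  gt <- make_gt(rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
                n1 = 7, n2 = 6, type = "mei")
  sh <- sharing_partition(gt)
  expect_equal(sh$pct_private_pop1, 100)

  # fixed difference
  gt2 <- make_gt(rbind(rep(c(2, 0), c(7, 6))), n1 = 7, n2 = 6,
                 type = "mei")
  expect_equal(sharing_partition(gt2)$pct_fixed_diff, 100)

  # 10-locus hand fixture: 3 private FL, 2 private Gulf, 1 fixed, 4 shared
  dos <- rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(2, 1, 0, 0),   # private pop1
    c(0, 0, 1, 0), c(0, 0, 0, 2),                  # private pop2
    c(2, 2, 0, 0),                                 # fixed difference
    c(1, 0, 1, 0), c(2, 0, 0, 1), c(1, 1, 1, 1), c(2, 2, 2, 2))  # shared
  gt3 <- make_gt(dos, n1 = 2, n2 = 2, type = "mei")
  sh3 <- sharing_partition(gt3)
  expect_equal(unname(sh3$counts), c(3L, 2L, 1L, 4L))
  expect_equal(sh3$pct_private_pop1 + sh3$pct_private_pop2 +
                 sh3$pct_fixed_diff + sh3$pct_shared, 100)
})

test_that("exact signed-rank test enumerates the sign-assignment null", {
  # 13 uniformly positive pairs: V = 13 * 14 / 2, p = 2 / 2^13
  r <- wilcoxon_signed_rank_exact(seq(0.1, 1.3, by = 0.1))
  expect_equal(r$V, 91)
  expect_equal(r$p, 2 / 2^13, tolerance = 1e-12)
  expect_true(r$exact)

  # 3 positive pairs: V = 6, p = 2/8 by enumerating the 8 sign patterns
  r3 <- wilcoxon_signed_rank_exact(c(1, 2, 3))
  expect_equal(r3$V, 6)
  expect_equal(r3$p, 0.25)

  # single positive pair: two-sided p capped at 1
  r1 <- wilcoxon_signed_rank_exact(1)
  expect_equal(r1$V, 1)
  expect_equal(r1$p, 1.0)

  # zero differences are dropped; all-zero input errors
  rz <- wilcoxon_signed_rank_exact(c(0, 1, 2, 3))
  expect_equal(rz$n_zero_dropped, 1L)
  expect_equal(rz$V, 6)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)), "zero")

  # agrees with the reference implementation on random data
  set.seed(4)
  for (i in 1:5) {
    d <- round(rnorm(12), 3)
    d <- d[d != 0]
    ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
    ours <- wilcoxon_signed_rank_exact(d)
    expect_equal(ours$V, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("rank-sum test matches enumeration and the reference", {
  # x = {1,2} vs y = {3,4}: most extreme of the 6 orderings, p = 1/3
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  # identical multisets: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))$p, 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  set.seed(8)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  ours <- wilcoxon_rank_sum(x, y)
  expect_equal(ours$W, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})
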