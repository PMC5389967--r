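test_that("filter_snps applies every threshold site-wise", {
  # three records: clean SNP, indel, SNP with one low-GQ genotype
  gt <- make_gt(rbind(c(0, 1, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 1)),
                n1 = 2, n2 = 2)
  gt$sites$alt[2L] <- "GT"                  # indel
  gt$gq[3L, 2L] <- 15                       # below min_gq = 20
  out <- filter_snps(gt, min_dp = 6, min_gq = 20, min_q = 20)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$id, "s1")
})

test_that("filter_snps with zero thresholds is the identity", {
  gt <- make_gt(rbind(c(0, 1, 0, 1), c(2, 1, 0, 0)), n1 = 2, n2 = 2)
  out <- filter_snps(gt, min_dp = 0, min_gq = 0, min_q = 0,
                     min_fraction_called = 0, biallelic_only = FALSE,
                     remove_indels = FALSE)
  expect_equal(out$dosage, gt$dosage)
  expect_equal(out$sites, gt$sites)
})

test_that("a single missing genotype drops the site under require-all-called", {
  gt <- make_gt(rbind(c(0, 1, 0, 1), c(0, NA, 0, 1)), n1 = 2, n2 = 2)
  out <- filter_snps(gt)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$id, "s1")
})

test_that("sites without depth/quality annotations are rejected, not fatal", {
  gt <- make_gt(rbind(c(0, 1, 0, 1), c(0, 1, 1, 1)), n1 = 2, n2 = 2)
  gt$dp[2L, 1L] <- NA
  expect_message(out <- filter_snps(gt), "DP/GQ")
  expect_equal(out$sites$id, "s1")
})

test_that("filtering is idempotent", {
  set.seed(5)
  gen <- generate_snp_dataset(constant_model(5000), n_sites = 40,
                              dir = withr::local_tempdir(), dirty = TRUE)
  pm <- read_population_map(gen$popmap)
  raw <- read_snp_vcf(gen$vcf, pm)
  once <- filter_snps(raw)
  twice <- filter_snps(once)
  expect_identical(once$dosage, twice$dosage)
  expect_identical(once$sites, twice$sites)
})

test_that("thin_snps keeps ordinals 1, 1+step, ... and errors on step < 1", {
  gt <- make_gt(matrix(rep(c(0L, 1L, 0L, 1L), each = 2500), ncol = 4),
                n1 = 2, n2 = 2)
  out <- thin_snps(gt, 1000)
  expect_equal(n_sites(out), 3L)
  expect_equal(out$sites$pos, gt$sites$pos[c(1L, 1001L, 2001L)])
  expect_identical(thin_snps(gt, 1)$sites, gt$sites)
  expect_error(thin_snps(gt, 0), "step")
})

test_that("thin_snps output size is ceil(n / step) for many (n, step)", {
  for (n in c(1L, 7L, 100L, 999L)) {
    gt <- make_gt(matrix(1L, n, 4), n1 = 2, n2 = 2)
    for (step in c(1L, 2L, 7L, 100L, 1000L)) {
      expect_equal(n_sites(thin_snps(gt, step)), ceiling(n / step),
                   info = sprintf("n=%d step=%d", n, step))
    }
  }
})

test_that("merge_mei_callsets unions families and enforces coverage/quality", {
  a <- make_gt(matrix(c(1L, 0L, 0L, 1L), 3, 4, byrow = TRUE), n1 = 2,
               n2 = 2, type = "mei", family = "famA",
               pos = c(1000L, 2000L, 3000L))
  b <- make_gt(matrix(c(0L, 1L, 1L, 0L), 4, 4, byrow = TRUE), n1 = 2,
               n2 = 2, type = "mei", family = "famB",
               pos = c(11000L, 12000L, 13000L, 14000L))
  merged <- merge_mei_callsets(list(a, b))
  expect_equal(n_sites(merged), 7L)
  expect_setequal(unique(merged$sites$family), c("famA", "famB"))

  # missing genotype and low-quality flag both remove a locus
  b$dosage[1L, 1L] <- NA
  b$sites$filter[2L] <- "lc"
  merged2 <- merge_mei_callsets(list(a, b))
  expect_equal(n_sites(merged2), 5L)
  merged3 <- merge_mei_callsets(list(a, b), require_full_coverage = FALSE)
  expect_equal(n_sites(merged3), 7L)
})

test_that("merge_mei_callsets names the offending callset on sample mismatch", {
  a <- make_gt(rbind(c(1L, 0L, 0L, 1L)), n1 = 2, n2 = 2, type = "mei")
  b <- make_gt(rbind(c(1L, 0L, 1L)), n1 = 2, n2 = 1, type = "mei")
  expect_error(merge_mei_callsets(list(a, b)), "callset 2")
})

test_that("dedup_nearby keeps the longest record of a chained cluster", {
  gt <- make_gt(rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L)), n1 = 2,
                n2 = 2, type = "mei", pos = c(100L, 130L))
  gt$sites$length <- c(500L, 3000L)
  out <- dedup_nearby(gt, 50)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$length, 3000L)

  # outside the window both survive
  gt2 <- gt
  gt2$sites$pos <- c(100L, 200L)
  expect_equal(n_sites(dedup_nearby(gt2, 50)), 2L)

  # transitive chain 100/140/180: one cluster, longest (3 kb) survives
  gt3 <- make_gt(matrix(1L, 3, 4), n1 = 2, n2 = 2, type = "mei",
                 pos = c(100L, 140L, 180L))
  gt3$sites$length <- c(1000L, 2000L, 3000L)
  out3 <- dedup_nearby(gt3, 50)
  expect_equal(n_sites(out3), 1L)
  expect_equal(out3$sites$pos, 180L)
})

test_that("dedup_nearby leaves no two records within the window", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 50L
    pos <- sort(sample.int(3000L, n))
    gt <- make_gt(matrix(1L, n, 4), n1 = 2, n2 = 2, type = "mei",
                  pos = pos)
    gt$sites$length <- sample(100:5000, n)
    out <- dedup_nearby(gt, 50)
    gaps <- diff(out$sites$pos)
    expect_true(all(gaps > 50))
  }
})

test_that("VCF round-trip reproduces positions, genotypes and lengths", {
  set.seed(21)
  gen <- generate_mei_dataset(
    desk_model(),
    families = data.frame(family = "CR1AC01", clade = "CR1", n_loci = 25L),
    dir = withr::local_tempdir())
  tab <- gen$tables[[1L]]
  path <- file.path(withr::local_tempdir(), "rt.vcf")
  write_vcf(tab, path)
  rt <- read_mei_vcf(path, tab$popmap)
  expect_identical(rt$sites$pos, tab$sites$pos)
  expect_identical(rt$dosage, tab$dosage)
  expect_identical(rt$sites$length, as.numeric(tab$sites$length))
  expect_identical(rt$sites$family, tab$sites$family)
})
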