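test_that("generated SNP VCFs pass the filtering recipe untouched", {
  set.seed(81)
  td <- withr::local_tempdir()
  gen <- generate_snp_dataset(desk_model(), n_sites = 120, dir = td)
  pm <- read_population_map(gen$popmap)
  raw <- read_snp_vcf(gen$vcf, pm)
  flt <- filter_snps(raw, min_dp = 6, min_gq = 20, min_q = 20)
  expect_equal(n_sites(flt), 120L)
  # spectra of the written file equal the generating table's tallies
  expect_identical(site_sfs(raw, "FLORIDA")$counts,
                   site_sfs(gen$table, "FLORIDA")$counts)
})

test_that("dirty mode injects records the filters must remove", {
  set.seed(82)
  td <- withr::local_tempdir()
  gen <- generate_snp_dataset(desk_model(), n_sites = 60, dir = td,
                              dirty = TRUE)
  pm <- read_population_map(gen$popmap)
  raw <- read_snp_vcf(gen$vcf, pm)
  expect_gt(n_sites(raw), 60L)
  flt <- filter_snps(raw)
  expect_equal(n_sites(flt), 60L)
})

test_that("generators are pure functions of the seed", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  set.seed(17); g1 <- generate_snp_dataset(desk_model(), 50, dir = td1)
  set.seed(17); g2 <- generate_snp_dataset(desk_model(), 50, dir = td2)
  expect_identical(readLines(g1$vcf), readLines(g2$vcf))
  fams <- data.frame(family = "RTE-1", clade = "RTE1", n_loci = 30L)
  set.seed(18); m1 <- generate_mei_dataset(desk_model(), fams, dir = td1)
  set.seed(18); m2 <- generate_mei_dataset(desk_model(), fams, dir = td2)
  expect_identical(readLines(m1$paths[[1]]), readLines(m2$paths[[1]]))
})

test_that("selection weight has the right neutral limit and shape", {
  q <- seq(0.05, 0.95, by = 0.05)
  expect_equal(selection_weight(q, 0), rep(1, length(q)))
  # gamma -> 0 continuously approaches 1
  expect_equal(selection_weight(q, -1e-8), rep(1, length(q)),
               tolerance = 1e-6)
  # purifying selection down-weights common variants monotonically
  w <- selection_weight(q, -10)
  expect_true(all(diff(w) < 0))
  expect_true(all(w <= 1 + 1e-12))
})

test_that("neutral generation reproduces the coalescent spectrum", {
  set.seed(83)
  m <- desk_model()
  fams <- data.frame(family = "CR1AC01", clade = "CR1", n_loci = 4000L)
  gen <- generate_mei_dataset(m, fams, gamma = 0,
                              dir = withr::local_tempdir())
  k_gen <- rowSums(linepopgen:::pop_dosage(gen$tables[[1]])) # pooled dosage
  s <- simulate_sfs(m, 7, 6, 4000)
  k_ref <- s$counts[, "k1"] + s$counts[, "k2"]
  tab <- rbind(tabulate(k_gen, 25L), tabulate(k_ref, 25L))
  chi <- suppressWarnings(stats::chisq.test(tab[, colSums(tab) > 0]))
  expect_gt(chi$p.value, 0.01)
})

test_that("purifying selection shifts frequencies down, monotonically in gamma", {
  set.seed(84)
  m <- desk_model()
  fams <- data.frame(family = "CR1AC01", clade = "CR1", n_loci = 1500L)
  mean_freq <- vapply(c(0, -5, -20), function(g) {
    gen <- generate_mei_dataset(m, fams, gamma = g,
                                dir = withr::local_tempdir())
    mean(rowSums(linepopgen:::pop_dosage(gen$tables[[1]])) / 26)
  }, numeric(1))
  expect_true(all(diff(mean_freq) < 0))
  # stronger selection also raises the singleton fraction
  set.seed(84)
  gen0 <- generate_mei_dataset(m, fams, gamma = 0,
                               dir = withr::local_tempdir())
  gen20 <- generate_mei_dataset(m, fams, gamma = -20,
                                dir = withr::local_tempdir())
  singleton <- function(gen) {
    mean(rowSums(linepopgen:::pop_dosage(gen$tables[[1]])) == 1)
  }
  expect_gt(singleton(gen20), singleton(gen0))
})

test_that("truncation models produce the documented length shapes", {
  set.seed(85)
  # bimodal L1: a mode under 1 kb and a mode near full length
  l1 <- draw_lengths(default_truncation_model("L1"), 4000)
  expect_gt(mean(l1 < 1000), 0.3)
  expect_gt(mean(l1 > 6400), 0.3)
  expect_lt(mean(l1 >= 1000 & l1 <= 6400), 0.1)
  # linearly decreasing CR1: short fragments dominate; bins aligned to the
  # truncated support (50 bp minimum, complete-element mass excluded)
  cr1 <- draw_lengths(default_truncation_model("CR1"), 4000)
  h <- hist(cr1[cr1 < 5225], breaks = seq(50, 5225, by = 575),
            plot = FALSE)$counts
  expect_true(all(diff(h) < 0))   # strictly decreasing across coarse bins
  # full fractions calibrated per clade (90% rule, family max = full length)
  lengths <- family_length_table(c("RTE-1", "CR1"), c(3900, 5800))
  rte <- draw_lengths(default_truncation_model("RTE1"), 4000)
  expect_equal(mean(rte >= 0.9 * 3900), 0.62, tolerance = 0.1)
  expect_equal(mean(cr1 >= 0.9 * 5800), 0.09, tolerance = 0.35)
})

test_that("trigger_dedup places pairs inside the 50 bp window", {
  set.seed(86)
  fams <- data.frame(family = "L2AC09", clade = "L2", n_loci = 20L)
  gen <- generate_mei_dataset(desk_model(), fams, trigger_dedup = TRUE,
                              dir = withr::local_tempdir())
  tab <- gen$tables[[1]]
  dd <- dedup_nearby(tab, 50)
  expect_equal(n_sites(dd), 10L)        # every pair collapsed
  expect_true(all(diff(dd$sites$pos) > 50))
})

test_that("table fixtures are written as readable TSVs", {
  td <- withr::local_tempdir()
  paths <- generate_table_fixtures(td)
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  back <- utils::read.table(paths[1L], header = TRUE, sep = "\t")
  expect_equal(sum(back$n_polymorphic), 46616L)
})
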