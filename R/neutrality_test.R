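#' Simulated null distribution of a statistic under the fitted demography
#'
#' For each of `n_sims` simulations: draw one parameter vector uniformly
#' from the per-parameter 95% CI ranges, simulate `n_loci` unlinked
#' polymorphic sites (one conditioned mutation each, matching the
#' ascertainment of the observed loci), and compute the statistic --
#' multi-locus Tajima's D or mean pairwise diversity in one population, or
#' the mean per-site Weir-Cockerham F_ST between the two.  Conditioning on
#' `n_loci`, the observed number of polymorphic loci in the family under
#' test, makes the null distribution family specific.
#'
#' Tajima's D is undefined when a simulated replicate has no site
#' segregating in the focal population; such replicates return `NA` and
#' are excluded, with the count reported.  `n_loci = 1` is legal but the
#' distribution is degenerate-variance; a warning is issued.
#'
#' @param ci_ranges named list or lo/hi matrix of parameter ranges (use
#'   degenerate ranges `c(x, x)` to pin a parameter).
#' @param base_model an `im_model` supplying non-sampled parameters.
#' @param n_loci number of unlinked polymorphic loci per simulation.
#' @param n1,n2 diploid sample sizes.
#' @param statistic `"tajima_d"`, `"fst"`, or `"pi"`.
#' @param population 1 or 2: which population for D / pi.
#' @param n_sims number of simulations (5,000 at full scale).
#' @return a list of class `null_distribution`: `values`, `statistic`,
#'   `n_na`, and a `provenance` record (ranges, n_loci, n_sims).
#' @export
family_null <- function(ci_ranges, base_model, n_loci, n1 = 7, n2 = 6,
                        statistic = c("tajima_d", "fst", "pi"),
                        population = 1, n_sims = 5000) {
  statistic <- match.arg(statistic)
  if (length(ci_ranges) == 0L) stop("empty CI ranges")
  if (is.matrix(ci_ranges)) {
    ci_ranges <- stats::setNames(
      lapply(seq_len(nrow(ci_ranges)),
             function(i) c(ci_ranges[i, 1L], ci_ranges[i, 2L])),
      rownames(ci_ranges))
  }
  stopifnot(n_loci >= 1)
  if (n_loci == 1L && statistic == "tajima_d") {
    warning("n_loci = 1: Tajima's D null distribution is degenerate")
  }
  h <- c(2L * n1, 2L * n2)
  values <- rep(NA_real_, n_sims)
  for (i in seq_len(n_sims)) {
    draw <- vapply(ci_ranges, function(b) stats::runif(1, b[1], b[2]),
                   numeric(1))
    model <- set_model_params(base_model, draw)
    k <- cpp_sim_counts(unclass(model), h[1L], h[2L], as.integer(n_loci))
    values[i] <- switch(statistic,
      tajima_d = {
        kk <- k[, population]
        n <- h[population]
        if (any(kk > 0 & kk < n)) {
          tajimas_d_from_counts(kk, n)$D
        } else NA_real_
      },
      pi = {
        kk <- k[, population]
        n <- h[population]
        mean(2 * kk * (n - kk) / (n * (n - 1)))
      },
      fst = mean_fst_from_counts(k, n1, n2))
  }
  n_na <- sum(is.na(values))
  structure(list(values = values[!is.na(values)], statistic = statistic,
                 n_na = n_na,
                 provenance = list(ci_ranges = ci_ranges, n_loci = n_loci,
                                   n_sims = n_sims, n1 = n1, n2 = n2,
                                   population = population)),
            class = "null_distribution")
}

# mean per-site WC F_ST from haploid derived counts, pairing chromosomes
# at random into diploids (hypergeometric heterozygote counts)
mean_fst_from_counts <- function(k, n1, n2) {
  d1 <- dosage_from_counts(k[, 1L], n1)
  d2 <- dosage_from_counts(k[, 2L], n2)
  comp <- wc_components(d1, d2)
  denom <- comp$a + comp$b + comp$c
  per_site <- ifelse(denom == 0, NA_real_, comp$a / denom)
  mean(per_site, na.rm = TRUE)
}

dosage_from_counts <- function(k, n_dip) {
  h <- 2L * n_dip
  t(vapply(k, function(ki) {
    hap <- integer(h)
    if (ki > 0) hap[sample.int(h, ki)] <- 1L
    hap[seq_len(n_dip) * 2L - 1L] + hap[seq_len(n_dip) * 2L]
  }, integer(n_dip)))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null distribution of %s: %d values (n_loci = %s, %d NA dropped)\n",
    x$statistic, length(x$values),
    if (!is.null(x$provenance$n_loci)) x$provenance$n_loci else "?",
    x$n_na))
  print(summary(x$values))
  invisible(x)
}

#' Empirical p-value against a simulated null
#'
#' Uses the add-one rule p = (r + 1)/(N + 1), where r counts simulated
#' values at least as extreme as the observation in the chosen tail, so a
#' finite simulation never reports p = 0.  `"two_sided"` doubles the
#' smaller tail, capped at 1.
#'
#' @param observed observed statistic value.
#' @param null a `null_distribution` (or numeric vector).
#' @param tail `"lower"`, `"upper"`, or `"two_sided"`.  Lower is the
#'   default for Tajima's D and F_ST: purifying selection predicts an
#'   excess of rare variants (negative D) and reduced differentiation.
#' @return the empirical p-value.
#' @export
empirical_p <- function(observed, null,
                        tail = c("lower", "upper", "two_sided")) {
  tail <- match.arg(tail)
  v <- if (inherits(null, "null_distribution")) null$values else null
  if (length(v) == 0L) stop("empty null distribution")
  N <- length(v)
  p_lo <- (sum(v <= observed) + 1) / (N + 1)
  p_hi <- (sum(v >= observed) + 1) / (N + 1)
  switch(tail,
         lower = p_lo,
         upper = p_hi,
         two_sided = min(1, 2 * min(p_lo, p_hi)))
}

#' Significance stars for a p-value
#' @param p p-value(s).
#' @return character: `***` < 0.001, `**` < 0.01, `*` < 0.05, else "".
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' SNP-bootstrap null distribution of Tajima's D
#'
#' Non-parametric alternative to the model-based null: repeatedly draw a
#' chromosome, a set size uniform on `set_size_range`, and a contiguous
#' run of that many SNPs starting at a random position, and compute the
#' multi-locus Tajima's D of the run in the selected population.
#' Chromosomes shorter than the drawn set size are redrawn, up to
#' `max_retries` per set.
#'
#' @param snps a filtered SNP `genotype_table`.
#' @param population population label (default first).
#' @param set_size_range `c(min, max)` SNPs per set (default 100-500).
#' @param n_sets number of bootstrap sets.
#' @param max_retries redraw cap per set.
#' @return a `null_distribution` of Tajima's D values.
#' @export
snp_bootstrap_null <- function(snps, population = NULL,
                               set_size_range = c(100, 500),
                               n_sets = 1000, max_retries = 100) {
  if (is.null(population)) population <- pop_labels(snps)[1L]
  d <- pop_dosage(snps, population)
  n <- 2L * ncol(d)
  k_all <- rowSums(d)
  chrom <- snps$sites$chrom
  idx_by_chrom <- split(seq_len(nrow(d)), chrom)
  chrom_sizes <- lengths(idx_by_chrom)
  if (max(chrom_sizes) < set_size_range[1L]) {
    stop("no chromosome has at least ", set_size_range[1L], " SNPs")
  }
  values <- rep(NA_real_, n_sets)
  for (i in seq_len(n_sets)) {
    sizes <- seq(set_size_range[1L], set_size_range[2L])
    for (try in seq_len(max_retries)) {
      ch <- names(idx_by_chrom)[sample.int(length(idx_by_chrom), 1L)]
      size <- sizes[sample.int(length(sizes), 1L)]
      if (chrom_sizes[[ch]] >= size) break
      if (try == max_retries) {
        stop("could not draw a SNP set after ", max_retries, " retries")
      }
    }
    idx <- idx_by_chrom[[ch]]
    start <- sample.int(length(idx) - size + 1L, 1L)
    kk <- k_all[idx[start:(start + size - 1L)]]
    values[i] <- if (any(kk > 0 & kk < n)) {
      tajimas_d_from_counts(kk, n)$D
    } else NA_real_
  }
  n_na <- sum(is.na(values))
  structure(list(values = values[!is.na(values)], statistic = "tajima_d",
                 n_na = n_na,
                 provenance = list(set_size_range = set_size_range,
                                   n_sets = n_sets,
                                   population = population)),
            class = "null_distribution")
}

#' Neutrality test report for a set of groups
#'
#' Convenience wrapper producing the per-group table: observed statistic,
#' null mean, empirical p and significance stars.
#'
#' @param groups named list; each element a list with `observed` (the
#'   observed statistic) and `n_loci`.
#' @param ci_ranges,base_model,n1,n2,statistic,population,n_sims passed to
#'   [family_null()].
#' @param tail passed to [empirical_p()].
#' @return data.frame with columns `group`, `statistic`, `observed`,
#'   `null_mean`, `p`, `stars`.
#' @export
neutrality_report <- function(groups, ci_ranges, base_model, n1 = 7,
                              n2 = 6, statistic = "tajima_d",
                              population = 1, n_sims = 5000,
                              tail = "lower") {
  rows <- lapply(names(groups), function(g) {
    null <- family_null(ci_ranges, base_model, groups[[g]]$n_loci,
                        n1 = n1, n2 = n2, statistic = statistic,
                        population = population, n_sims = n_sims)
    p <- empirical_p(groups[[g]]$observed, null, tail = tail)
    data.frame(group = g, statistic = statistic,
               observed = groups[[g]]$observed,
               null_mean = mean(null$values), p = p,
               stars = significance_stars(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
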