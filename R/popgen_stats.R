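#' Site frequency spectrum of one population
#'
#' Tallies, for every allele count k = 0..n (n = sampled chromosomes), the
#' number of sites at which the counted allele appears k times in the
#' selected population.  For MEI tables the insertion allele is the derived
#' allele (the reference genome lacks the insertion), so `"derived"`
#' counts insertion dosage directly; `"minor_folded"` folds the spectrum
#' about n/2, the convention used for SNP minor-allele spectra.
#'
#' @param x a `genotype_table` with no missing genotypes.
#' @param population population label, or `NULL` for the pooled sample.
#' @param polarization `"derived"` or `"minor_folded"`.
#' @return an object of class `sfs`: integer vector `counts` indexed
#'   0..n, with attributes `n` and `polarization`.
#' @export
site_sfs <- function(x, population = NULL,
                     polarization = c("derived", "minor_folded")) {
  polarization <- match.arg(polarization)
  d <- pop_dosage(x, population)
  if (anyNA(d)) stop("missing genotypes present; filter first")
  n <- 2L * ncol(d)
  k <- as.integer(rowSums(d))
  if (polarization == "minor_folded") k <- pmin(k, n - k)
  counts <- tabulate(k + 1L, nbins = n + 1L)
  structure(list(counts = counts, n = n, polarization = polarization),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("site frequency spectrum (%s), n = %d chromosomes\n",
              x$polarization, x$n))
  v <- x$counts
  names(v) <- 0:x$n
  print(v)
  invisible(x)
}

#' Number of polymorphic sites recorded in a spectrum
#' @param s an `sfs`.
#' @return integer: sum of the entries with 0 < k < n.
#' @export
sfs_segregating <- function(s) {
  sum(s$counts[seq(2L, s$n, by = 1L)])
}

#' Joint site frequency spectrum over two populations
#'
#' @param x a `genotype_table` covering exactly two populations.
#' @param pops optional character vector of the two population labels in
#'   (pop1, pop2) order; defaults to FLORIDA, GULF order when present.
#' @return a (n1+1) x (n2+1) integer matrix of derived-allele counts, of
#'   class `joint_sfs`.
#' @export
joint_sfs <- function(x, pops = NULL) {
  if (is.null(pops)) pops <- pop_labels(x)
  if (length(pops) != 2L) stop("exactly two populations required")
  d1 <- pop_dosage(x, pops[1L]); d2 <- pop_dosage(x, pops[2L])
  if (anyNA(d1) || anyNA(d2)) stop("missing genotypes present; filter first")
  n1 <- 2L * ncol(d1); n2 <- 2L * ncol(d2)
  k1 <- as.integer(rowSums(d1)); k2 <- as.integer(rowSums(d2))
  m <- matrix(0L, n1 + 1L, n2 + 1L,
              dimnames = list(0:n1, 0:n2))
  tab <- table(factor(k1, levels = 0:n1), factor(k2, levels = 0:n2))
  m[] <- as.integer(tab)
  structure(m, class = c("joint_sfs", "matrix"), pops = pops)
}

# joint SFS directly from a matrix of (k1, k2) counts (simulator output)
joint_sfs_from_counts <- function(k, n1, n2) {
  m <- matrix(0L, n1 + 1L, n2 + 1L, dimnames = list(0:n1, 0:n2))
  tab <- table(factor(k[, 1L], levels = 0:n1), factor(k[, 2L], levels = 0:n2))
  m[] <- as.integer(tab)
  structure(m, class = c("joint_sfs", "matrix"))
}

#' Mean pairwise difference per locus
#'
#' Average over loci of the per-locus mean pairwise difference
#' 2k(n-k) / (n(n-1)), where k is the derived-allele count among the n
#' chromosomes of the selected population.  This is the per-locus
#' heterozygosity-like quantity reported for polymorphic insertions.
#'
#' @param x a `genotype_table` (typically restricted to the loci of one
#'   group beforehand).
#' @param population population label or `NULL` for the pooled sample.
#' @return the mean over loci, a single number.
#' @export
mean_pairwise_diff <- function(x, population = NULL) {
  d <- pop_dosage(x, population)
  if (nrow(d) == 0L) stop("empty table: mean pairwise difference undefined")
  if (anyNA(d)) stop("missing genotypes present; filter first")
  n <- 2L * ncol(d)
  k <- rowSums(d)
  mean(2 * k * (n - k) / (n * (n - 1)))
}

#' Tajima's D with all intermediate components
#'
#' Computes the classical normalized difference between the mean pairwise
#' diversity (pi) and Watterson's estimator (S / a1) over the sites of the
#' selected population, using the standard constants
#' a1, a2, b1, b2, c1, c2, e1, e2 derived from the sample size.  Negative
#' values indicate an excess of rare variants (population expansion or
#' purifying/positive selection); positive values indicate a deficit
#' (contraction or balancing selection).
#'
#' @param x a `genotype_table`.
#' @param population population label or `NULL` for the pooled sample.
#' @return a list of class `tajima_d`: `n`, `S`, `pi_sum`, `theta_w`, the
#'   eight constants, and `D`.
#' @export
tajimas_d <- function(x, population = NULL) {
  d <- pop_dosage(x, population)
  if (anyNA(d)) stop("missing genotypes present; filter first")
  n <- 2L * ncol(d)
  k <- rowSums(d)
  tajimas_d_from_counts(k, n)
}

# core: D from a vector of per-site derived counts among n chromosomes
tajimas_d_from_counts <- function(k, n) {
  if (n < 4L) stop("Tajima's D needs at least 4 chromosomes")
  seg <- k > 0L & k < n
  S <- sum(seg)
  if (S < 1L) stop("no segregating sites in this population: D undefined")
  pi_sum <- sum(2 * k[seg] * (n - k[seg]) / (n * (n - 1)))
  cst <- tajima_constants(n)
  varD <- cst$e1 * S + cst$e2 * S * (S - 1)
  D <- (pi_sum - S / cst$a1) / sqrt(varD)
  structure(c(list(n = n, S = S, pi_sum = pi_sum,
                   theta_w = S / cst$a1), cst, list(D = D)),
            class = "tajima_d")
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' @export
print.tajima_d <- function(x, ...) {
  cat(sprintf("Tajima's D = %.4f  (n = %d, S = %d, pi = %.3f, thetaW = %.3f)\n",
              x$D, x$n, x$S, x$pi_sum, x$theta_w))
  invisible(x)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Per-site variance-components estimator for a biallelic site sampled in
#' two populations of diploids, using allele frequencies and observed
#' heterozygosities.  Sites monomorphic across both populations have an
#' undefined (0/0) estimate and are excluded from the mean; negative
#' per-site estimates are retained (set `clamp = TRUE` to floor at 0).
#'
#' @param x a `genotype_table` covering exactly two populations, each with
#'   at least two diploids.
#' @param clamp floor negative per-site estimates at zero.
#' @return a list of class `fst_result`: `per_site` (per-site estimates,
#'   `NA` where undefined), `mean_fst` (arithmetic mean over defined
#'   sites), `weighted_fst` (ratio-of-sums estimate sum(a)/sum(a+b+c)).
#' @export
weir_cockerham_fst <- function(x, clamp = FALSE) {
  pops <- pop_labels(x)
  if (length(pops) != 2L) stop("exactly two populations required")
  d1 <- pop_dosage(x, pops[1L]); d2 <- pop_dosage(x, pops[2L])
  if (ncol(d1) < 2L || ncol(d2) < 2L) {
    stop("each population needs at least 2 diploids")
  }
  if (anyNA(d1) || anyNA(d2)) stop("missing genotypes present; filter first")
  comp <- wc_components(d1, d2)
  denom <- comp$a + comp$b + comp$c
  per_site <- ifelse(denom == 0, NA_real_, comp$a / denom)
  if (clamp) per_site <- pmax(per_site, 0)
  structure(list(per_site = per_site,
                 a = comp$a, b = comp$b, c = comp$c,
                 mean_fst = mean(per_site, na.rm = TRUE),
                 weighted_fst = sum(comp$a) / sum(denom)),
            class = "fst_result")
}

# Weir & Cockerham (1984) a, b, c for two populations of diploids
wc_components <- function(d1, d2) {
  r <- 2
  nmat <- cbind(ncol(d1), ncol(d2))      # diploids per pop (constant here)
  n1 <- ncol(d1); n2 <- ncol(d2)
  p1 <- rowSums(d1) / (2 * n1)
  p2 <- rowSums(d2) / (2 * n2)
  h1 <- rowMeans(d1 == 1L)
  h2 <- rowMeans(d2 == 1L)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST: mean = %.4f, weighted = %.4f (%d sites, %d defined)\n",
              x$mean_fst, x$weighted_fst, length(x$per_site),
              sum(!is.na(x$per_site))))
  invisible(x)
}

#' Private / fixed / shared partition of variant loci
#'
#' Classifies each locus that carries the variant (derived / insertion)
#' allele in at least one population as: private to pop1, private to pop2,
#' a fixed difference (frequency 1 in one population and 0 in the other),
#' or shared (the allele present in both populations).  Percentages are
#' over the classified loci.
#'
#' @param x a `genotype_table` with two populations.
#' @param pops optional (pop1, pop2) label order.
#' @return a list of class `sharing_partition` with the four percentages,
#'   the per-category counts, and `n_loci`.
#' @export
sharing_partition <- function(x, pops = NULL) {
  if (is.null(pops)) pops <- pop_labels(x)
  if (length(pops) != 2L) stop("exactly two populations required")
  d1 <- pop_dosage(x, pops[1L]); d2 <- pop_dosage(x, pops[2L])
  if (anyNA(d1) || anyNA(d2)) stop("missing genotypes present; filter first")
  n1 <- 2L * ncol(d1); n2 <- 2L * ncol(d2)
  k1 <- rowSums(d1); k2 <- rowSums(d2)
  variant <- k1 > 0 | k2 > 0
  k1 <- k1[variant]; k2 <- k2[variant]
  fixed_diff <- (k1 == n1 & k2 == 0) | (k1 == 0 & k2 == n2)
  private1 <- k1 > 0 & k2 == 0 & !fixed_diff
  private2 <- k2 > 0 & k1 == 0 & !fixed_diff
  shared <- k1 > 0 & k2 > 0
  n <- sum(variant)
  counts <- c(private_pop1 = sum(private1), private_pop2 = sum(private2),
              fixed_diff = sum(fixed_diff), shared = sum(shared))
  structure(list(pct_private_pop1 = 100 * counts[["private_pop1"]] / n,
                 pct_private_pop2 = 100 * counts[["private_pop2"]] / n,
                 pct_fixed_diff = 100 * counts[["fixed_diff"]] / n,
                 pct_shared = 100 * counts[["shared"]] / n,
                 counts = counts, n_loci = n, pops = pops),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat(sprintf("allele sharing over %d variant loci (%s vs %s):\n",
              x$n_loci, x$pops[1L], x$pops[2L]))
  cat(sprintf("  private %s: %.2f%%   private %s: %.2f%%\n",
              x$pops[1L], x$pct_private_pop1, x$pops[2L], x$pct_private_pop2))
  cat(sprintf("  fixed differences: %.2f%%   shared: %.2f%%\n",
              x$pct_fixed_diff, x$pct_shared))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired test on (x, y) pairs: V is the sum of the ranks (midranks under
#' ties) of the positive differences; zero differences are dropped before
#' ranking.  The two-sided p-value is exact -- the null distribution over
#' all 2^n sign assignments -- for n <= 25 pairs without ties, and uses
#' the normal approximation with continuity and tie correction otherwise.
#'
#' @param x,y paired numeric vectors, or `y = NULL` to test differences
#'   `x` against zero.
#' @return a list of class `signed_rank_test`: `V`, `p`, `n_used`,
#'   `n_zero_dropped`, `exact`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1L)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences are zero: test undefined")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    # dsignrank/psignrank enumerate the 2^n equiprobable sign assignments
    p_lo <- stats::psignrank(V, n)
    p_hi <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(V = V, p = p, n_used = n, n_zero_dropped = n_zero,
                 exact = exact),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.3g (%s, n = %d%s)\n",
              x$V, x$p, if (x$exact) "exact" else "normal approx.",
              x$n_used,
              if (x$n_zero_dropped > 0)
                sprintf(", %d zero difference(s) dropped", x$n_zero_dropped)
              else ""))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum statistic with midranks for ties; W is the rank sum
#' of the first sample minus its minimum n_x(n_x+1)/2 (the Mann-Whitney U
#' convention).  Exact p for small tie-free samples, normal approximation
#' with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return a list of class `rank_sum_test`: `W`, `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx + ny <= 50L) {
    p_lo <- stats::pwilcox(W, nx, ny)
    p_hi <- stats::pwilcox(W - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(W = W, p = p, exact = exact), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.3g (%s)\n",
              x$W, x$p, if (x$exact) "exact" else "normal approx."))
  invisible(x)
}
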