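#' Simulate genealogy summaries under the IM model
#'
#' Runs the backward-in-time structured coalescent for samples of `n1` and
#' `n2` diploids (2 chromosomes each) under an [im_model()]: pairwise
#' coalescence at rate 1/(2N) within each population, per-lineage
#' migration until the split, and pooling into the ancestral population at
#' `T_split`.  Returns per-replicate TMRCA and total branch length in
#' generations -- the summaries with closed neutral forms (for one
#' constant-size population, E\[TMRCA\] = 4N(1 - 1/n) and
#' E\[total length\] = 4N sum_{i=1}^{n-1} 1/i).
#'
#' Randomness comes from R's global RNG: call `set.seed()` for
#' reproducibility.
#'
#' @param model an `im_model`.
#' @param n1,n2 diploid sample sizes (defaults 7 and 6; `n2 = 0` samples
#'   only pop1).
#' @param n_reps number of independent genealogies.
#' @param ploidy chromosomes sampled per individual; set `ploidy = 1` to
#'   sample single lineages (handy for closed-form pair checks).
#' @return data.frame with columns `tmrca`, `total_length`.
#' @export
simulate_site_genealogy <- function(model, n1 = 7, n2 = 6, n_reps = 1,
                                    ploidy = 2) {
  validate_im_model(model)
  stopifnot(n1 >= 0, n2 >= 0, n1 + n2 >= 1, n_reps >= 1,
            ploidy %in% c(1, 2))
  as.data.frame(cpp_sim_tree_stats(unclass(model), as.integer(ploidy * n1),
                                   as.integer(ploidy * n2),
                                   as.integer(n_reps)))
}

#' Simulate site frequency spectra under the IM model
#'
#' Simulates `num_sites` unlinked sites (an independent genealogy each).
#' In `"fixed_sites"` mode exactly one mutation is placed uniformly on the
#' total branch length of each genealogy, so every site is polymorphic in
#' the pooled sample -- the conditioning that matches SNP and MEI
#' ascertainment.  In `"theta_poisson"` mode each site receives
#' Poisson(theta/(4 N_ref) x total branch length) mutations, for
#' expectation checks against Watterson's formula (`theta` is the
#' population-scaled 4 N_ref mu per site; `N_ref` defaults to the current
#' size of pop1).
#'
#' @param model an `im_model`.
#' @param n1,n2 diploid sample sizes.
#' @param num_sites number of unlinked sites.
#' @param mode `"fixed_sites"` or `"theta_poisson"`.
#' @param theta population-scaled mutation rate per site (theta_poisson
#'   mode only).
#' @param N_ref reference diploid size scaling `theta`.
#' @return a list of class `sim_sfs`: `counts` (matrix of per-site derived
#'   chromosome counts `k1`, `k2`; in theta_poisson mode one row per
#'   mutation with a `site` column), `joint` (a `joint_sfs`), `sfs1`,
#'   `sfs2` (per-population `sfs`), `n1`, `n2`.
#' @export
simulate_sfs <- function(model, n1 = 7, n2 = 6, num_sites = 1000,
                         mode = c("fixed_sites", "theta_poisson"),
                         theta = 1, N_ref = model$N_cur_p1) {
  validate_im_model(model)
  mode <- match.arg(mode)
  stopifnot(num_sites >= 1)
  h1 <- 2L * n1; h2 <- 2L * n2
  if (mode == "fixed_sites") {
    k <- cpp_sim_counts(unclass(model), h1, h2, as.integer(num_sites))
    colnames(k) <- c("k1", "k2")
  } else {
    mu <- theta / (4 * N_ref)
    k <- cpp_sim_poisson(unclass(model), h1, h2, as.integer(num_sites), mu)
    colnames(k) <- c("site", "k1", "k2")
  }
  kk <- k[, c("k1", "k2"), drop = FALSE]
  joint <- joint_sfs_from_counts(kk, h1, h2)
  sfs1 <- structure(list(counts = tabulate(kk[, 1L] + 1L, nbins = h1 + 1L),
                         n = h1, polarization = "derived"), class = "sfs")
  sfs2 <- structure(list(counts = tabulate(kk[, 2L] + 1L, nbins = h2 + 1L),
                         n = h2, polarization = "derived"), class = "sfs")
  structure(list(counts = k, joint = joint, sfs1 = sfs1, sfs2 = sfs2,
                 n1 = n1, n2 = n2, mode = mode),
            class = "sim_sfs")
}

#' Simulate diploid genotypes under the IM model
#'
#' As [simulate_sfs()] in fixed-sites mode, but the haploid copies of each
#' population are paired at random into diploid genotypes and returned as
#' a [genotype_table()] (VCF-compatible, positions spaced `spacing_bp`
#' apart on one synthetic chromosome).  Because each site's mutation is
#' exchangeable across chromosomes, carriers are assigned by drawing k1 /
#' k2 chromosomes uniformly at random per site.
#'
#' @inheritParams simulate_sfs
#' @param pop_labels labels for the two populations.
#' @param chrom chromosome name used in the output table.
#' @param spacing_bp distance between consecutive sites.
#' @return a `genotype_table` of type `"snp"` (with passing DP/GQ set).
#' @export
simulate_genotypes <- function(model, n1 = 7, n2 = 6, num_sites = 1000,
                               pop_labels = c("FLORIDA", "GULF"),
                               chrom = "chr1", spacing_bp = 1000L) {
  sim <- simulate_sfs(model, n1, n2, num_sites, mode = "fixed_sites")
  counts_to_genotype_table(sim$counts, n1, n2, pop_labels, chrom,
                           spacing_bp)
}

# shared by simulate_genotypes and the synthetic-data generators
counts_to_genotype_table <- function(k, n1, n2, pop_labels, chrom,
                                     spacing_bp, type = "snp",
                                     sites_extra = NULL,
                                     start_pos = 1L) {
  num_sites <- nrow(k)
  h1 <- 2L * n1; h2 <- 2L * n2
  samples <- c(if (n1 > 0) paste0("FL", seq_len(n1)),
               if (n2 > 0) paste0("GU", seq_len(n2)))
  dosage <- matrix(0L, num_sites, n1 + n2,
                   dimnames = list(NULL, samples))
  for (s in seq_len(num_sites)) {
    hap1 <- integer(h1); hap2 <- integer(h2)
    if (k[s, "k1"] > 0) hap1[sample.int(h1, k[s, "k1"])] <- 1L
    if (h2 > 0 && k[s, "k2"] > 0) hap2[sample.int(h2, k[s, "k2"])] <- 1L
    dos1 <- if (n1 > 0) hap1[seq_len(n1) * 2L - 1L] + hap1[seq_len(n1) * 2L]
            else integer(0)
    dos2 <- if (n2 > 0) hap2[seq_len(n2) * 2L - 1L] + hap2[seq_len(n2) * 2L]
            else integer(0)
    dosage[s, ] <- c(dos1, dos2)
  }
  pm <- population_map(samples, c(rep(pop_labels[1L], n1),
                                  rep(pop_labels[2L], n2)))
  pos <- start_pos + (seq_len(num_sites) - 1L) * spacing_bp
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      id = paste0(type, seq_len(num_sites)),
                      ref = "A", alt = if (type == "snp") "G" else "<INS>",
                      qual = 100, filter = "PASS",
                      stringsAsFactors = FALSE)
  if (!is.null(sites_extra)) sites <- cbind(sites, sites_extra)
  if (type == "snp") {
    dp <- matrix(30, num_sites, n1 + n2, dimnames = dimnames(dosage))
    gq <- matrix(99, num_sites, n1 + n2, dimnames = dimnames(dosage))
    genotype_table(sites, dosage, pm, dp = dp, gq = gq, type = "snp")
  } else {
    genotype_table(sites, dosage, pm, type = "mei")
  }
}
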