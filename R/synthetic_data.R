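#' Clade-specific insertion-length (truncation) models
#'
#' LINE insertions are truncated at their 5' end when reverse
#' transcription terminates prematurely, so the observed insertion length
#' measures how far the reaction ran from the 3' end.  Three shapes cover
#' the clades analysed here:
#'
#' * `"uniform_plus_full"` (R4, RTE-1): truncation can happen anywhere
#'   along the element -- lengths uniform on (`min_length_bp`,
#'   `full_length_bp`) -- plus a point mass `full_fraction` of complete
#'   elements.
#' * `"linear_decreasing"` (CR1, L2): the probability of truncation
#'   decreases with distance to the 3' end, giving a length density that
#'   falls off linearly with length (mostly short fragments), plus a
#'   small complete-element mass.
#' * `"bimodal"` (L1): elements either truncate early (under ~1 kb) or
#'   run to (near) completion, with few in between.
#'
#' Default `full_fraction` values are calibrated to the observed
#' complete-element fractions: RTE-1 0.62, L1 0.43, R4 0.41, CR1 0.09,
#' L2 0.07.
#'
#' @param shape one of the three shapes above.
#' @param full_length_bp full element length (bp).
#' @param full_fraction probability mass at (near) full length.
#' @param min_length_bp smallest truncated length generated.
#' @return a list of class `truncation_model`.
#' @export
truncation_model <- function(shape = c("uniform_plus_full",
                                       "linear_decreasing", "bimodal"),
                             full_length_bp, full_fraction,
                             min_length_bp = 50) {
  shape <- match.arg(shape)
  stopifnot(full_length_bp > 0, full_fraction >= 0, full_fraction <= 1,
            min_length_bp > 0, min_length_bp < full_length_bp)
  structure(list(shape = shape, full_length_bp = full_length_bp,
                 full_fraction = full_fraction,
                 min_length_bp = min_length_bp),
            class = "truncation_model")
}

#' @rdname truncation_model
#' @param clade clade label: `"L1"`, `"L2"`, `"CR1"`, `"R4"`, `"RTE1"`.
#' @export
default_truncation_model <- function(clade) {
  switch(clade,
    R4 = truncation_model("uniform_plus_full", 3800, 0.41),
    RTE1 = ,
    `RTE-1` = truncation_model("uniform_plus_full", 3900, 0.62),
    CR1 = truncation_model("linear_decreasing", 5800, 0.09),
    L2 = truncation_model("linear_decreasing", 6300, 0.07),
    L1 = truncation_model("bimodal", 6800, 0.43),
    stop("no default truncation model for clade '", clade, "'"))
}

#' Draw insertion lengths from a truncation model
#' @param model a `truncation_model`.
#' @param n number of lengths.
#' @return integer vector of lengths in bp.
#' @export
draw_lengths <- function(model, n) {
  full <- stats::runif(n) < model$full_fraction
  L <- model$full_length_bp
  lo <- model$min_length_bp
  trunc_len <- switch(model$shape,
    uniform_plus_full = stats::runif(n, lo, L),
    # density falling linearly from lo to L: inverse-CDF of the triangle
    linear_decreasing = L - (L - lo) * sqrt(stats::runif(n)),
    bimodal = {
      # truncated mode: early termination, < 1 kb
      pmin(stats::runif(n, lo, 1000), L)
    })
  len <- ifelse(full,
                # complete elements: within the last 5% of full length
                round(stats::runif(n, 0.95 * L, L)),
                round(trunc_len))
  as.integer(pmin(pmax(len, lo), L))
}

#' Purifying-selection weight on a derived-allele frequency
#'
#' Ratio of the Wright-Fisher diffusion sojourn density for a new
#' semidominant mutation with population-scaled selection coefficient
#' `gamma` to the neutral density 1/q:
#' w(q) = (1 - exp(-gamma (1 - q))) / ((1 - q)(1 - exp(-gamma))).
#' The neutral limit gamma -> 0 gives w = 1 everywhere; for gamma < 0
#' (purifying selection) w decreases with q, down-weighting common
#' variants.  Used as the acceptance weight of the rejection sampler in
#' [generate_mei_dataset()].
#'
#' @param q derived-allele frequency in (0, 1).
#' @param gamma population-scaled selection coefficient (0 = neutral,
#'   negative = purifying).
#' @return numeric weights, same length as `q`.
#' @export
selection_weight <- function(q, gamma) {
  if (gamma == 0) return(rep(1, length(q)))
  # expm1 keeps the ratio stable for |gamma| small and large
  w <- -expm1(-gamma * (1 - q)) / ((1 - q) * -expm1(-gamma))
  w[q >= 1] <- 0
  w
}

#' Generate a synthetic SNP dataset (VCF + population map)
#'
#' Simulates `n_sites` unlinked polymorphic SNPs for `n1` + `n2` diploids
#' under the demographic model and writes a filter-clean VCF (constant
#' passing DP/GQ) plus a two-column population map.  With
#' `dirty = TRUE`, extra sub-threshold records (low GQ, low DP, an indel,
#' a missing genotype) are interleaved to exercise [filter_snps()].
#'
#' @param model an `im_model` (default: the fitted anole model).
#' @param n_sites number of SNPs.
#' @param n1,n2 diploid sample sizes.
#' @param dir output directory.
#' @param dirty also write records that must be filtered out.
#' @param chrom chromosome name.
#' @return list with paths `vcf` and `popmap`, and the `genotype_table`.
#' @export
generate_snp_dataset <- function(model = anole_im_model(), n_sites = 1000,
                                 n1 = 7, n2 = 6, dir = ".",
                                 dirty = FALSE, chrom = "chr1") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- simulate_genotypes(model, n1, n2, n_sites, chrom = chrom)
  if (dirty) {
    bad <- tab[seq_len(min(4L, n_sites))]
    bad$sites$pos <- max(tab$sites$pos) + seq_len(n_sites(bad)) * 1000L
    bad$sites$id <- paste0("bad", seq_len(n_sites(bad)))
    bad$gq[1L, 1L] <- 5            # genotype quality below threshold
    if (n_sites(bad) >= 2L) bad$dp[2L, 2L] <- 2      # depth below threshold
    if (n_sites(bad) >= 3L) bad$sites$alt[3L] <- "GT" # indel
    if (n_sites(bad) >= 4L) bad$dosage[4L, 1L] <- NA  # missing genotype
    tab <- genotype_table(rbind(tab$sites, bad$sites),
                          rbind(tab$dosage, bad$dosage),
                          tab$popmap,
                          dp = rbind(tab$dp, bad$dp),
                          gq = rbind(tab$gq, bad$gq), type = "snp")
  }
  vcf <- file.path(dir, "snps.vcf")
  popmap <- file.path(dir, "popmap.tsv")
  write_vcf(tab, vcf)
  write_population_map(tab$popmap, popmap)
  list(vcf = vcf, popmap = popmap, table = tab)
}

#' Generate synthetic per-family MEI datasets
#'
#' For each requested family: simulates `n_loci` unlinked
#' insertion-presence sites under the demographic model, optionally
#' distorts the site frequencies by purifying selection (rejection
#' sampling with [selection_weight()] on the pooled derived frequency, so
#' the neutral limit `gamma = 0` reproduces the coalescent frequencies
#' exactly), draws insertion lengths from the family's truncation model,
#' and writes one MELT-style VCF per family.  Loci are spaced well beyond
#' the deduplication window by default; `trigger_dedup = TRUE` instead
#' places pairs within 50 bp to exercise [dedup_nearby()].
#'
#' @param model an `im_model`.
#' @param families data.frame with columns `family`, `clade`, `n_loci`;
#'   optionally a list-column `trunc` of [truncation_model()]s (defaults
#'   per clade).
#' @param gamma population-scaled selection coefficient (<= 0).
#' @param n1,n2 diploid sample sizes.
#' @param dir output directory.
#' @param trigger_dedup place loci in 50 bp pairs.
#' @param max_tries rejection-sampling cap per accepted locus.
#' @return list with `paths` (named per family), `tables` (the
#'   `genotype_table`s), and `popmap` path.
#' @export
generate_mei_dataset <- function(model = anole_im_model(), families,
                                 gamma = 0, n1 = 7, n2 = 6, dir = ".",
                                 trigger_dedup = FALSE, max_tries = 1000) {
  stopifnot(all(c("family", "clade", "n_loci") %in% names(families)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h1 <- 2L * n1; h2 <- 2L * n2
  n_tot <- h1 + h2
  paths <- character(0)
  tables <- list()
  pm_path <- file.path(dir, "popmap.tsv")
  for (i in seq_len(nrow(families))) {
    fam <- families$family[i]
    clade <- families$clade[i]
    n_loci <- families$n_loci[i]
    stopifnot(n_loci >= 1)
    trunc <- if (!is.null(families$trunc)) families$trunc[[i]] else
      default_truncation_model(clade)
    k <- draw_selected_counts(model, h1, h2, n_loci, gamma, max_tries)
    lens <- draw_lengths(trunc, n_loci)
    # each family gets its own position block so the 50 bp dedup rule does
    # not collapse loci across families
    offset <- (i - 1L) * 10000L * (max(families$n_loci) + 1L)
    if (trigger_dedup) {
      # consecutive loci 30 bp apart in pairs, pairs 10 kb apart
      pos <- offset + cumsum(ifelse(seq_len(n_loci) %% 2L == 0L, 30L, 10000L))
    } else {
      pos <- offset + seq_len(n_loci) * 10000L
    }
    tab <- counts_to_genotype_table(
      k, n1, n2, c("FLORIDA", "GULF"), chrom = "chr1", spacing_bp = 1L,
      type = "mei",
      sites_extra = data.frame(family = fam, clade = clade,
                               length = lens))
    tab$sites$pos <- as.integer(pos)
    tab$sites$id <- paste0(fam, "_", seq_len(n_loci))
    path <- file.path(dir, paste0("mei_", gsub("[^A-Za-z0-9_.-]", "_", fam),
                                  ".vcf"))
    write_vcf(tab, path)
    paths[fam] <- path
    tables[[fam]] <- tab
  }
  write_population_map(tables[[1L]]$popmap, pm_path)
  list(paths = paths, tables = tables, popmap = pm_path)
}

# rejection sampler: neutral conditioned counts accepted with probability
# proportional to the selection weight of the pooled derived frequency
draw_selected_counts <- function(model, h1, h2, n_loci, gamma, max_tries) {
  n_tot <- h1 + h2
  if (gamma == 0) {
    k <- cpp_sim_counts(unclass(model), h1, h2, as.integer(n_loci))
    colnames(k) <- c("k1", "k2")
    return(k)
  }
  # attainable pooled frequencies and the weight ceiling over them
  q_grid <- seq_len(n_tot - 1L) / n_tot
  w_max <- max(selection_weight(q_grid, gamma))
  out <- matrix(0L, n_loci, 2L, dimnames = list(NULL, c("k1", "k2")))
  filled <- 0L
  for (round in seq_len(max_tries)) {
    need <- n_loci - filled
    batch <- max(need * 2L, 16L)
    k <- cpp_sim_counts(unclass(model), h1, h2, as.integer(batch))
    q <- (k[, 1L] + k[, 2L]) / n_tot
    acc <- stats::runif(batch) < selection_weight(q, gamma) / w_max
    n_acc <- sum(acc)
    if (n_acc > 0L) {
      take <- min(n_acc, need)
      out[filled + seq_len(take), ] <- k[which(acc)[seq_len(take)], ,
                                         drop = FALSE]
      filled <- filled + take
    }
    if (filled == n_loci) return(out)
  }
  stop("rejection sampling did not fill ", n_loci, " loci after ",
       max_tries, " rounds; gamma = ", gamma,
       " is too extreme for this sample size -- use a milder coefficient")
}
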