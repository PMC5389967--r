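# Shared fixture builders and independent oracles.

# genotype table from a dosage matrix (rows = sites); n1/n2 diploids per pop
make_gt <- function(dosage, n1, n2, type = "snp", family = "FAM1",
                    clade = "CR1", length = 1000L, dp = 30, gq = 99,
                    qual = 100, chrom = "chr1", pos = NULL,
                    filter = "PASS") {
  dosage <- rbind(dosage)
  storage.mode(dosage) <- "integer"
  nsamp <- n1 + n2
  stopifnot(ncol(dosage) == nsamp)
  samples <- c(sprintf("FL%d", seq_len(n1)), sprintf("GU%d", seq_len(n2)))
  colnames(dosage) <- samples
  pm <- population_map(samples, c(rep("FLORIDA", n1), rep("GULF", n2)))
  ns <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(ns) * 1000L
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      id = paste0("s", seq_len(ns)), ref = "A",
                      alt = if (type == "snp") "G" else "<INS>",
                      qual = rep_len(qual, ns),
                      filter = rep_len(filter, ns),
                      stringsAsFactors = FALSE)
  if (type == "mei") {
    sites$family <- rep_len(family, ns)
    sites$clade <- rep_len(clade, ns)
    sites$length <- rep_len(as.integer(length), ns)
    genotype_table(sites, dosage, pm, type = "mei")
  } else {
    dpm <- matrix(rep_len(dp, ns * nsamp), ns, nsamp,
                  dimnames = list(NULL, samples))
    gqm <- matrix(rep_len(gq, ns * nsamp), ns, nsamp,
                  dimnames = list(NULL, samples))
    genotype_table(sites, dosage, pm, dp = dpm, gq = gqm, type = "snp")
  }
}

# brute-force mean pairwise difference: expand each site's allele count into
# haplotypes and enumerate every chromosome pair
oracle_pi <- function(k_per_site, n) {
  per_site <- vapply(k_per_site, function(k) {
    hap <- c(rep(1L, k), rep(0L, n - k))
    pairs <- utils::combn(n, 2)
    mean(hap[pairs[1L, ]] != hap[pairs[2L, ]])
  }, numeric(1))
  mean(per_site)
}

# independent transcription of the Tajima (1989) D formula
oracle_tajima_d <- function(k_per_site, n) {
  seg <- k_per_site > 0 & k_per_site < n
  S <- sum(seg)
  pi_sum <- sum(2 * k_per_site[seg] * (n - k_per_site[seg]) / (n * (n - 1)))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# small neutral-equilibrium desk model used by several property suites
desk_model <- function() {
  im_model(N_cur_p1 = 10000, N_cur_p2 = 4000, N_anc_p1 = 10000,
           N_anc_p2 = 4000, N_anc_all = 8000, T_change_p1 = 0,
           T_change_p2 = 0, T_split = 20000, m12 = 1e-5, m21 = 1e-5)
}
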