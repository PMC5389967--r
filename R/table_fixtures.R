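#' Published summary tables of the anole LINE survey
#'
#' Machine-readable copies of the published summary tables, for worked
#' examples and consistency checks: per-clade copy numbers and full-length
#' counts (`"clades"`), per-individual insertion counts with population
#' and sequencing depth (`"individuals"`), the per-group summary
#' statistics table (`"summary_stats"`), and per-family copy numbers for
#' the L1, L2 and RTE clades (`"families"`).
#'
#' Two printed inconsistencies are carried as printed rather than
#' resolved: the stated Florida per-individual mean (10,022) differs from
#' the mean of the individuals column (71,545 / 7 = 10,220.7), and the
#' clade table's R4 full-length count (712) is the summary table's R4
#' truncated locus count while its full-length locus count is 1,017.
#'
#' @param which which table to return.
#' @return a data.frame.
#' @export
anole_tables <- function(which = c("clades", "individuals",
                                   "summary_stats", "families")) {
  which <- match.arg(which)
  switch(which,
         clades = anole_table_clades(),
         individuals = anole_table_individuals(),
         summary_stats = anole_table_summary(),
         families = anole_table_families())
}

anole_table_clades <- function() {
  data.frame(
    clade = c("R4", "RTE", "CR1", "L2", "L1"),
    n_families = c(2L, 2L, 4L, 17L, 20L),
    n_rt_hits = c(7682L, 18554L, 86802L, 38607L, 7441L),
    n_copies_reference = c(3000L, 3516L, 1594L, 3800L, 806L),
    n_full_length_reference = c(994L, 217L, 117L, 380L, 170L),
    full_length_min_bp = c(3800L, 3200L, 4600L, 4800L, 5200L),
    full_length_max_bp = c(3800L, 3900L, 5800L, 6300L, 6800L),
    n_polymorphic = c(1729L, 3367L, 27802L, 11210L, 2508L),
    n_full_length_polymorphic = c(712L, 1782L, 2578L, 769L, 1089L),
    stringsAsFactors = FALSE)
}

anole_table_individuals <- function() {
  data.frame(
    sample_id = c("AC_36_1", "AC_38_4", "AC_8_13", "AC_8_8", "AC_27_3",
                  "AC_27_4", "CC3", "CC8", "SB3", "SB4", "TV8", "VB6",
                  "VB7"),
    population = c(rep("GULF", 6L), rep("FLORIDA", 7L)),
    depth = c(15L, 10L, 9L, 16L, 10L, 10L, 16L, 16L, 12L, 8L, 8L, 10L, 9L),
    n_insertions_present = c(7557L, 6367L, 6402L, 7849L, 5626L, 5135L,
                             9969L, 11965L, 11839L, 8371L, 8557L, 10393L,
                             10451L),
    n_full_length_present = c(839L, 699L, 629L, 861L, 565L, 500L, 863L,
                              1130L, 1069L, 621L, 740L, 890L, 924L),
    stringsAsFactors = FALSE)
}

anole_table_summary <- function() {
  # columns: pi over All / Florida / Gulf, Tajima's D per population,
  # locus counts, sharing percentages, mean F_ST; subset column: All
  # loci, FL (full length), TR (truncated)
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
group subset pi_all pi_florida pi_gulf D_florida D_gulf n_loci pct_private_florida pct_private_gulf pct_fixed pct_shared mean_fst
SNPs All 0.21 0.22 0.36 -0.62 0.47 314575 60.25 15.85 0.19 23.72 0.12
L1 All 0.15 0.22 0.31 -1.39 -0.48 2508 65.67 19.46 0 14.87 0.04
L1_AC1to16 FL 0.15 0.21 0.32 -1.46 -0.13 454 71.81 18.5 0 9.69 0.04
L1_AC1to16 TR 0.18 0.25 0.30 -0.95 -0.5 1062 59.13 15.35 0 25.52 0.04
L1_AC17to20 FL 0.11 0.17 0.28 -2.06 -0.78 635 68.82 27.09 0 4.09 0.03
L1_AC17to20 TR 0.14 0.20 0.31 -1.6 -0.24 357 71.71 19.33 0 8.96 0.04
L2 All 0.15 0.23 0.28 -1.27 -0.74 11210 61.06 23.76 0 15.18 0.05
L2 FL 0.13 0.20 0.28 -1.65 -0.75 769 67.1 25.1 0 7.80 0.04
L2 TR 0.15 0.23 0.28 -1.24 -0.74 10440 60.61 23.66 0 15.73 0.05
CR1 All 0.15 0.22 0.31 -1.31 -0.29 27802 70.35 18.02 0.02 11.62 0.05
CR1 FL 0.14 0.21 0.30 -1.51 -0.49 2578 68 23.27 0 8.73 0.05
CR1 TR 0.16 0.22 0.31 -1.29 -0.27 25224 70.59 17.48 0.02 11.91 0.05
R4 All 0.17 0.24 0.25 -1.04 -1.1 1729 49.1 20.76 0 30.13 0.03
R4 FL 0.16 0.23 0.25 -1.16 -1.21 1017 47.79 20.94 0 31.27 0.02
R4 TR 0.18 0.25 0.27 -0.87 -0.93 712 50.98 20.51 0 28.51 0.04
RTE-1 All 0.11 0.18 0.23 -1.91 -1.42 2853 62.57 33.16 0 4.28 0.02
RTE-1 FL 0.11 0.18 0.22 -2.00 -1.52 1774 61.72 35.17 0 3.10 0.02
RTE-1 TR 0.12 0.19 0.24 -1.77 -1.23 1079 63.95 29.84 0 6.21 0.02
RTEBovB All 0.25 0.31 0.34 -0.08 0.06 514 37.74 12.84 0 49.42 0.05
RTEBovB FL 0.27 0.38 0.33 0.76 -0.06 8 25 25 0 50.00 0.14
RTEBovB TR 0.25 0.31 0.34 -0.1 0.06 506 37.94 12.65 0 49.41 0.05
")
  tab
}

anole_table_families <- function() {
  l1 <- c(L1AC01 = 68, L1AC02 = 18, L1AC03 = 0, L1AC04 = 43, L1AC05 = 27,
          L1AC06 = 87, L1AC07 = 532, L1AC08 = 95, L1AC09 = 82,
          L1AC10 = 0, L1AC11 = 90, L1AC12 = 52, L1AC13 = 103,
          L1AC14 = 85, L1AC15 = 181, L1AC16 = 53, L1AC17 = 763,
          L1AC18 = 0, L1AC19 = 23, L1AC20 = 206)
  l2 <- c(L2AC01 = 507, L2AC02 = 336, L2AC03 = 301, L2AC04 = 504,
          L2AC05 = 276, L2AC06 = 569, L2AC07 = 543, L2AC08 = 1424,
          L2AC09 = 1661, L2AC10 = 131, L2AC11 = 720, L2AC12 = 206,
          L2AC13 = 948, L2AC14 = 256, L2AC15 = 1177, L2AC16 = 388,
          L2AC17 = 1263)
  rte <- c(`RTE-1` = 2853, RTEBovB = 514)
  data.frame(
    family = c(names(l1), names(l2), names(rte)),
    clade = c(rep("L1", length(l1)), rep("L2", length(l2)),
              rep("RTE", length(rte))),
    copy_number = as.integer(c(l1, l2, rte)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the packaged tables to TSV files
#'
#' Emits all four fixture tables under `dir`, one TSV each, for use
#' outside R.
#'
#' @param dir output directory (created if absent).
#' @return character vector of the paths written.
#' @export
generate_table_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("clades", "individuals", "summary_stats", "families")
  paths <- file.path(dir, paste0("anole_table_", tables, ".tsv"))
  for (i in seq_along(tables)) {
    utils::write.table(anole_tables(tables[i]), paths[i], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
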