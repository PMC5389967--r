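#' Genotype tables and population maps
#'
#' A `genotype_table` is the package's central container: an ordered set of
#' biallelic sites (SNPs or MEI loci) with a per-sample dosage matrix
#' (0/1/2 copies of the alternate / insertion allele, `NA` for missing),
#' optional per-genotype depth and quality matrices, and a population map.
#' Coordinates are 1-based VCF point positions throughout.
#'
#' @param sites data.frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `qual`; MEI tables additionally carry `family`, `clade`, `length` and
#'   `filter`. Rows must be sorted by (chrom, pos).
#' @param dosage integer matrix, sites x samples, entries 0/1/2 or `NA`.
#' @param popmap population map, see [population_map()].
#' @param dp,gq optional numeric matrices of per-genotype depth and quality
#'   (same shape as `dosage`).
#' @param type `"snp"` or `"mei"`.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(sites, dosage, popmap, dp = NULL, gq = NULL,
                           type = c("snp", "mei")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(dosage), nrow(dosage) == nrow(sites))
  if (is.null(colnames(dosage))) stop("dosage must have sample column names")
  if (!all(colnames(dosage) %in% popmap$sample_id)) {
    stop("dosage samples missing from the population map: ",
         paste(setdiff(colnames(dosage), popmap$sample_id), collapse = ", "))
  }
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  popmap <- popmap[match(colnames(dosage), popmap$sample_id), , drop = FALSE]
  rownames(popmap) <- NULL
  structure(list(sites = sites, dosage = dosage, dp = dp, gq = gq,
                 popmap = popmap, type = type),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table (%s): %d sites x %d samples\n",
              x$type, nrow(x$sites), ncol(x$dosage)))
  tab <- table(x$popmap$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  genotype_table(x$sites[i, , drop = FALSE],
                 x$dosage[i, , drop = FALSE],
                 x$popmap,
                 dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
                 gq = if (!is.null(x$gq)) x$gq[i, , drop = FALSE],
                 type = x$type)
}

#' Number of sites in a genotype table
#' @param x a `genotype_table`.
#' @return integer site count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' Build a population map
#'
#' Maps each sample to one of two populations.  By convention the labels
#' are `"FLORIDA"` (East Florida) and `"GULF"` (Gulf-Atlantic), but any two
#' labels are accepted; every sample must appear exactly once.
#'
#' @param sample_id character vector of sample names.
#' @param population character vector of population labels, same length.
#' @return a data.frame of class `population_map`.
#' @export
population_map <- function(sample_id, population) {
  stopifnot(length(sample_id) == length(population))
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  pm <- data.frame(sample_id = as.character(sample_id),
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Read / write a two-column population map TSV
#' @param path file path; TSV with columns `sample_id`, `population`.
#' @return [read_population_map()] returns a `population_map`.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  population_map(tab$sample_id, tab$population)
}

#' @rdname read_population_map
#' @param pm a `population_map`.
#' @export
write_population_map <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# samples belonging to one population (or all, population = NULL)
pop_samples <- function(x, population = NULL) {
  if (is.null(population)) return(x$popmap$sample_id)
  keep <- x$popmap$population == population
  if (!any(keep)) {
    stop("unknown population '", population, "'; available: ",
         paste(unique(x$popmap$population), collapse = ", "))
  }
  x$popmap$sample_id[keep]
}

# dosage submatrix for a population
pop_dosage <- function(x, population = NULL) {
  x$dosage[, pop_samples(x, population), drop = FALSE]
}

# the two population labels, in stable order (pop1 first if present)
pop_labels <- function(x) {
  labs <- unique(x$popmap$population)
  pref <- c("FLORIDA", "GULF")
  c(intersect(pref, labs), setdiff(labs, pref))
}
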