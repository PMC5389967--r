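#' Family maximum-length table
#'
#' Maps each LINE family to the maximum (full) element length used by the
#' complete/truncated classification.  [default_family_lengths()] ships a
#' per-clade configuration derived from the published full-length ranges
#' of the anole LINE clades (R4 3.8 kb; RTE 3.2-3.9 kb; CR1 4.6-5.8 kb;
#' L2 4.8-6.3 kb; L1 5.2-6.8 kb); families absent from the configuration
#' fall back to the observed maximum in the data when
#' `observed_fallback = TRUE`.
#'
#' @param family character vector of family names.
#' @param max_length numeric vector of maximum lengths (bp), same length.
#' @return a named numeric vector of class `family_lengths`.
#' @export
family_length_table <- function(family, max_length) {
  stopifnot(length(family) == length(max_length), all(max_length > 0))
  out <- stats::setNames(as.numeric(max_length), as.character(family))
  class(out) <- "family_lengths"
  out
}

#' @rdname family_length_table
#' @export
default_family_lengths <- function() {
  clade_max <- c(L1 = 6800, L2 = 6300, CR1 = 5800, R4 = 3800,
                 RTE1 = 3900, RTEBovB = 3900)
  fams <- c(
    stats::setNames(rep(6800, 20), sprintf("L1AC%02d", 1:20)),
    stats::setNames(rep(6300, 17), sprintf("L2AC%02d", 1:17)),
    stats::setNames(rep(5800, 4), sprintf("CR1AC%02d", 1:4)),
    stats::setNames(rep(3800, 2), sprintf("R4AC%02d", 1:2)),
    c("RTE-1" = 3900, RTEBovB = 3900)
  )
  family_length_table(names(fams), fams)
}

lookup_max_length <- function(lengths, family, observed = NULL,
                              observed_fallback = TRUE) {
  hit <- match(family, names(lengths))
  out <- as.numeric(lengths)[hit]
  if (anyNA(out)) {
    if (observed_fallback && !is.null(observed)) {
      for (f in unique(family[is.na(out)])) {
        obs_max <- suppressWarnings(max(observed[family == f], na.rm = TRUE))
        if (is.finite(obs_max)) out[is.na(out) & family == f] <- obs_max
      }
    }
    if (anyNA(out)) {
      stop("no maximum length configured or observable for family: ",
           paste(unique(family[is.na(out)]), collapse = ", "))
    }
  }
  out
}

#' Classify insertions as complete or truncated
#'
#' An element is complete when its predicted length is at least
#' `threshold_fraction` (default 90%) of the maximum length of its family,
#' boundary inclusive; shorter elements are (5'-)truncated.
#'
#' @param x a `genotype_table` of type `"mei"`, or a data.frame with
#'   `family` and `length` columns.
#' @param lengths a [family_length_table()]; defaults to the packaged
#'   per-clade configuration.
#' @param threshold_fraction completeness threshold (default 0.9).
#' @param observed_fallback use the observed per-family maximum when a
#'   family is missing from `lengths`.
#' @return factor with levels `COMPLETE`, `TRUNCATED`, one per locus.
#' @export
classify_complete <- function(x, lengths = default_family_lengths(),
                              threshold_fraction = 0.9,
                              observed_fallback = TRUE) {
  s <- if (inherits(x, "genotype_table")) x$sites else x
  stopifnot(all(c("family", "length") %in% names(s)))
  max_len <- lookup_max_length(lengths, s$family, observed = s$length,
                               observed_fallback = observed_fallback)
  factor(ifelse(s$length >= threshold_fraction * max_len,
                "COMPLETE", "TRUNCATED"),
         levels = c("COMPLETE", "TRUNCATED"))
}

#' Per-individual insertion counts
#'
#' For every sample: the number of loci at which the individual carries at
#' least one insertion allele (dosage >= 1), in total and restricted to
#' complete (full-length) elements.
#'
#' @inheritParams classify_complete
#' @return data.frame with columns `sample_id`, `population`,
#'   `n_insertions_present`, `n_full_length_present`.
#' @export
per_individual_counts <- function(x, lengths = default_family_lengths(),
                                  threshold_fraction = 0.9) {
  cls <- classify_complete(x, lengths, threshold_fraction)
  present <- !is.na(x$dosage) & x$dosage >= 1L
  full <- cls == "COMPLETE"
  data.frame(sample_id = colnames(x$dosage),
             population = x$popmap$population,
             n_insertions_present = colSums(present),
             n_full_length_present = colSums(present[full, , drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-clade and per-family summaries of polymorphic insertions
#'
#' @inheritParams classify_complete
#' @param by `"clade"` or `"family"`.
#' @return data.frame with columns `group`, `n_polymorphic`,
#'   `n_full_length`, `fraction_full_length` (NA for empty groups).
#' @export
clade_summary <- function(x, lengths = default_family_lengths(),
                          threshold_fraction = 0.9,
                          by = c("clade", "family")) {
  by <- match.arg(by)
  cls <- classify_complete(x, lengths, threshold_fraction)
  g <- x$sites[[by]]
  groups <- unique(g)
  out <- data.frame(group = groups,
                    n_polymorphic = as.integer(table(g)[groups]),
                    n_full_length = vapply(groups, function(gr) {
                      sum(cls[g == gr] == "COMPLETE")
                    }, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$fraction_full_length <-
    ifelse(out$n_polymorphic > 0, out$n_full_length / out$n_polymorphic,
           NA_real_)
  out[order(out$group), , drop = FALSE]
}

#' Per-clade insertion-length histogram
#'
#' Counts insertions in half-open length bins `[lo, hi)` of width
#' `bin_width_bp` per clade, the tabular form of the clade length
#' distributions (truncation profiles).
#'
#' @inheritParams classify_complete
#' @param bin_width_bp bin width in bp (>= 1).
#' @return data.frame with columns `clade`, `bin_lo`, `bin_hi`, `count`
#'   (only occupied bins are listed).
#' @export
length_histogram <- function(x, bin_width_bp = 250) {
  stopifnot(bin_width_bp >= 1)
  s <- if (inherits(x, "genotype_table")) x$sites else x
  if (nrow(s) == 0L) {
    return(data.frame(clade = character(), bin_lo = numeric(),
                      bin_hi = numeric(), count = integer()))
  }
  bin <- floor(s$length / bin_width_bp)
  tab <- as.data.frame(table(clade = s$clade, bin = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(clade = tab$clade,
                    bin_lo = as.numeric(tab$bin) * bin_width_bp,
                    bin_hi = (as.numeric(tab$bin) + 1) * bin_width_bp,
                    count = as.integer(tab$Freq),
                    stringsAsFactors = FALSE)
  out[order(out$clade, out$bin_lo), , drop = FALSE]
}
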