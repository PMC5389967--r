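#' Two-population isolation-with-migration model
#'
#' Constructs and validates the demographic model used throughout the
#' package: two populations (pop1 = East Florida, pop2 = Gulf-Atlantic by
#' convention) that diverged from a common ancestral population `T_split`
#' generations ago, each with a single instantaneous size change, and
#' exchanging migrants at constant per-generation rates until the split.
#'
#' All sizes are **diploid** individuals.  Time is measured in generations
#' before the present.  Migration rates follow the *backward* convention of
#' coalescent simulators: `m12` is the per-generation probability that a
#' lineage currently in pop1 traces its ancestry to pop2 (forward in time,
#' pop1 receives migrants from pop2), and symmetrically for `m21`.
#'
#' @param N_cur_p1,N_cur_p2 current diploid sizes of pop1 and pop2.
#' @param N_anc_p1,N_anc_p2 diploid sizes of pop1/pop2 at founding, i.e. on
#'   the interval `[T_change_pX, T_split)` looking backward in time.
#' @param N_anc_all diploid size of the ancestral population (before the
#'   split, looking forward).
#' @param T_change_p1,T_change_p2 generations before present at which each
#'   population changed size (step change); must lie in `[0, T_split]`.
#' @param T_split generations before present of the population split.
#' @param m12,m21 backward per-lineage migration probabilities (see above).
#' @return an object of class `im_model` (a validated named list).
#' @examples
#' m <- im_model(N_cur_p1 = 1e4, N_cur_p2 = 1e4, N_anc_p1 = 1e4,
#'               N_anc_p2 = 1e4, N_anc_all = 1e4, T_change_p1 = 0,
#'               T_change_p2 = 0, T_split = 4e4, m12 = 0, m21 = 0)
#' @export
im_model <- function(N_cur_p1, N_cur_p2, N_anc_p1, N_anc_p2, N_anc_all,
                     T_change_p1, T_change_p2, T_split, m12 = 0, m21 = 0) {
  m <- list(N_cur_p1 = N_cur_p1, N_cur_p2 = N_cur_p2,
            N_anc_p1 = N_anc_p1, N_anc_p2 = N_anc_p2,
            N_anc_all = N_anc_all,
            T_change_p1 = T_change_p1, T_change_p2 = T_change_p2,
            T_split = T_split, m12 = m12, m21 = m21)
  validate_im_model(m)
  class(m) <- "im_model"
  m
}

validate_im_model <- function(m) {
  num <- vapply(m, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    stop("all model parameters must be finite scalars; offending: ",
         paste(names(m)[!num], collapse = ", "))
  }
  sizes <- c("N_cur_p1", "N_cur_p2", "N_anc_p1", "N_anc_p2", "N_anc_all")
  if (any(unlist(m[sizes]) <= 0)) stop("population sizes must be > 0")
  if (m$T_split < 0) stop("T_split must be >= 0")
  if (m$T_change_p1 < 0 || m$T_change_p1 > m$T_split ||
      m$T_change_p2 < 0 || m$T_change_p2 > m$T_split) {
    stop("size-change times must lie in [0, T_split]")
  }
  if (m$m12 < 0 || m$m12 >= 1 || m$m21 < 0 || m$m21 >= 1) {
    stop("migration rates must be in [0, 1)")
  }
  invisible(TRUE)
}

#' @export
print.im_model <- function(x, ...) {
  cat("Two-population isolation-with-migration model\n")
  cat(sprintf("  pop1: N %s -> %s (change %s ga)\n",
              format(x$N_anc_p1, big.mark = ","),
              format(x$N_cur_p1, big.mark = ","),
              format(x$T_change_p1, big.mark = ",")))
  cat(sprintf("  pop2: N %s -> %s (change %s ga)\n",
              format(x$N_anc_p2, big.mark = ","),
              format(x$N_cur_p2, big.mark = ","),
              format(x$T_change_p2, big.mark = ",")))
  cat(sprintf("  split: %s ga, ancestral N %s\n",
              format(x$T_split, big.mark = ","),
              format(x$N_anc_all, big.mark = ",")))
  cat(sprintf("  backward migration: m12 = %g, m21 = %g\n", x$m12, x$m21))
  invisible(x)
}

#' Fitted anole demographic model (maximum-likelihood point estimates)
#'
#' The isolation-with-migration model fitted to the anole SNP joint site
#' frequency spectrum: East Florida (pop1) expanded from ~751k to ~3.3M
#' diploids ~802k generations ago; Gulf-Atlantic (pop2) contracted from
#' ~1.42M to ~236k diploids ~274k generations ago; the split is fixed at
#' 1.34 million generations (1.34 Mya at one generation per year).
#' Forward-in-time rate labels ("Gulf from Florida") map to backward rates:
#' the rate at which a Gulf lineage traces back into Florida is `m21`.
#'
#' @param which `"ml"` for the point estimates, `"lo"`/`"hi"` for the
#'   bounds of the 95% confidence interval on each free parameter.
#' @return an `im_model`.
#' @seealso [anole_model_ci()] for the CI ranges in matrix form.
#' @export
anole_im_model <- function(which = c("ml", "lo", "hi")) {
  which <- match.arg(which)
  tab <- anole_model_ci()
  p <- tab[, switch(which, ml = "ml", lo = "lo", hi = "hi")]
  im_model(N_cur_p1 = p[["N_cur_p1"]], N_cur_p2 = p[["N_cur_p2"]],
           N_anc_p1 = p[["N_anc_p1"]], N_anc_p2 = p[["N_anc_p2"]],
           N_anc_all = p[["N_anc_all"]],
           T_change_p1 = p[["T_change_p1"]], T_change_p2 = p[["T_change_p2"]],
           T_split = 1.34e6, m12 = p[["m12"]], m21 = p[["m21"]])
}

#' 95% confidence ranges of the fitted anole demographic parameters
#'
#' @return a matrix with columns `lo`, `ml`, `hi` and one row per free
#'   parameter (the split time was fixed, not estimated).
#' @export
anole_model_ci <- function() {
  tab <- rbind(
    N_anc_p2    = c(379795,  1422722, 8838592),  # ancestral size, Gulf
    N_anc_p1    = c(366002,   751115, 1756393),  # ancestral size, Florida
    N_anc_all   = c(564492,  1167977, 1488644),  # ancestral size, all
    N_cur_p1    = c(1959085, 3316203, 4603720),  # current size, Florida
    N_cur_p2    = c(101238,   235789,  351645),  # current size, Gulf
    T_change_p2 = c(57331,    274157,  559121),  # time of size change, Gulf
    T_change_p1 = c(275163,   802462, 1110215),  # time of size change, FL
    m21         = c(2.96e-07, 3.94e-07, 5.51e-07),  # Gulf from Florida
    m12         = c(2.19e-07, 3.38e-07, 9.00e-07)   # Florida from Gulf
  )
  colnames(tab) <- c("lo", "ml", "hi")
  tab
}

#' Constant-size single-population model
#'
#' Degenerate `im_model` in which the split happens at time 0, so the whole
#' history is a single panmictic population of constant diploid size `N`.
#' Convenient for closed-form coalescent checks (E\[TMRCA\] = 4N(1 - 1/n)
#' generations, Watterson's E\[S\]).
#'
#' @param N constant diploid population size.
#' @return an `im_model`.
#' @export
constant_model <- function(N) {
  im_model(N_cur_p1 = N, N_cur_p2 = N, N_anc_p1 = N, N_anc_p2 = N,
           N_anc_all = N, T_change_p1 = 0, T_change_p2 = 0,
           T_split = 0, m12 = 0, m21 = 0)
}
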