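#' Composite log-likelihood of an observed joint SFS
#'
#' Multinomial composite log-likelihood sum(observed * log(p)) over the
#' polymorphic entries of the joint spectrum, treating sites as
#' independent.  The two monomorphic corners (derived allele absent
#' everywhere or fixed everywhere) are excluded, matching the
#' SNP-conditioned scheme in which every tallied site is polymorphic in
#' the pooled sample.  Expected probabilities of exactly zero at occupied
#' entries are floored at `floor` (default 1/(10 x `n_sim`), the number of
#' simulated sites behind the expectation) and the flooring is reported.
#'
#' @param observed a `joint_sfs` (or matrix) of observed counts.
#' @param expected_probs matrix of the same shape with expected entry
#'   probabilities summing to 1 over polymorphic entries.
#' @param n_sim number of simulated sites behind `expected_probs`, used
#'   for the default floor.
#' @param floor probability floor for zero-probability occupied entries.
#' @return a list: `log_cl`, `n_floored`.
#' @export
composite_log_likelihood <- function(observed, expected_probs,
                                     n_sim = NULL,
                                     floor = if (is.null(n_sim)) 1e-8 else
                                       1 / (10 * n_sim)) {
  if (!all(dim(observed) == dim(expected_probs))) {
    stop("observed and expected spectra have different shapes: ",
         paste(dim(observed), collapse = "x"), " vs ",
         paste(dim(expected_probs), collapse = "x"))
  }
  poly <- polymorphic_mask(dim(observed))
  obs <- as.vector(observed)[poly]
  p <- as.vector(expected_probs)[poly]
  floored <- obs > 0 & p <= 0
  p[floored] <- floor
  list(log_cl = sum(obs[obs > 0] * log(p[obs > 0])),
       n_floored = sum(floored))
}

polymorphic_mask <- function(dims) {
  mask <- matrix(TRUE, dims[1L], dims[2L])
  mask[1L, 1L] <- FALSE                 # derived absent everywhere
  mask[dims[1L], dims[2L]] <- FALSE     # derived fixed everywhere
  as.vector(mask)
}

#' Expected joint-SFS entry probabilities by simulation
#'
#' @param model an `im_model`.
#' @param n1,n2 diploid sample sizes.
#' @param n_sim number of simulated unlinked polymorphic sites.
#' @return matrix of entry probabilities (polymorphic entries sum to 1).
#' @export
expected_sfs_probs <- function(model, n1, n2, n_sim) {
  k <- cpp_sim_counts(unclass(model), 2L * n1, 2L * n2, as.integer(n_sim))
  m <- joint_sfs_from_counts(k, 2L * n1, 2L * n2)
  unclass(m) / sum(m)
}

#' Optimisation schedule presets
#'
#' The `"published"` preset mirrors the full-scale estimation protocol (40
#' cycles from 50,000 to 250,000 simulations per likelihood evaluation,
#' 100 independent replicates); `"desk"` is the package default sized for
#' interactive use and testing (10 cycles, 2,000 to 10,000 simulations,
#' 10 replicates).
#'
#' @param preset `"desk"` or `"published"`.
#' @param cycles,sims_start,sims_end,replicates overrides.
#' @return a named list understood by [fit_demography()].
#' @export
fit_schedule <- function(preset = c("desk", "published"), cycles = NULL,
                         sims_start = NULL, sims_end = NULL,
                         replicates = NULL) {
  preset <- match.arg(preset)
  s <- switch(preset,
    desk = list(cycles = 10L, sims_start = 2000L, sims_end = 10000L,
                replicates = 10L),
    published = list(cycles = 40L, sims_start = 50000L, sims_end = 250000L,
                     replicates = 100L))
  if (!is.null(cycles)) s$cycles <- as.integer(cycles)
  if (!is.null(sims_start)) s$sims_start <- as.integer(sims_start)
  if (!is.null(sims_end)) s$sims_end <- as.integer(sims_end)
  if (!is.null(replicates)) s$replicates <- as.integer(replicates)
  s
}

# replace free parameters in a model, clamping times into validity
set_model_params <- function(base, params) {
  m <- unclass(base)
  m[names(params)] <- as.list(unname(params))
  m$T_change_p1 <- min(max(m$T_change_p1, 0), m$T_split)
  m$T_change_p2 <- min(max(m$T_change_p2, 0), m$T_split)
  class(m) <- "im_model"
  validate_im_model(m)
  m
}

#' Fit demographic parameters to an observed joint SFS
#'
#' Simulation-based composite-likelihood estimation: in each cycle the
#' expected entry probabilities are re-estimated by coalescent simulation
#' at the cycle's simulation budget (growing linearly from `sims_start` to
#' `sims_end`), and a derivative-free coordinate search proposes
#' multiplicative updates on the log scale of each free parameter
#' (sizes, times and rates are positive and span decades).  All candidate
#' evaluations within a cycle reuse one random substream (common random
#' numbers), so comparisons between candidates are not swamped by
#' simulation noise, and the best composite likelihood is non-decreasing
#' over cycles.  The whole procedure is repeated `replicates` times from
#' random starting points and the replicate with the best final composite
#' likelihood wins.  The split time is typically held fixed (leave
#' `"T_split"` out of `free`) but may be freed for reduced models.
#'
#' @param observed a `joint_sfs` of observed counts (shape fixes the
#'   sample sizes).
#' @param base_model an `im_model` supplying every parameter not in
#'   `free`.
#' @param free character vector of free parameter names (subset of the
#'   `im_model` fields).
#' @param bounds named list of `c(lo, hi)` search bounds, one per free
#'   parameter.
#' @param schedule a [fit_schedule()].
#' @param step_start,step_end multiplicative proposal step at the first
#'   and last cycle.
#' @param verbose print per-cycle progress.
#' @return an object of class `demographic_fit`: `ml_model`, `estimates`,
#'   `log_cl`, `replicate_results`, `free`, `bounds`, `schedule`,
#'   `observed`, `n1`, `n2`.
#' @export
fit_demography <- function(observed, base_model, free, bounds,
                           schedule = fit_schedule("desk"),
                           step_start = 2, step_end = 1.15,
                           verbose = FALSE) {
  stopifnot(all(free %in% names(unclass(base_model))),
            all(free %in% names(bounds)))
  for (b in bounds) stopifnot(length(b) == 2L, all(is.finite(b)), b[1] > 0,
                              b[1] <= b[2])
  n1 <- (nrow(observed) - 1L) %/% 2L
  n2 <- (ncol(observed) - 1L) %/% 2L
  sims_at <- function(cy) {
    if (schedule$cycles == 1L) return(schedule$sims_end)
    round(schedule$sims_start + (schedule$sims_end - schedule$sims_start) *
            (cy - 1) / (schedule$cycles - 1))
  }
  step_at <- function(cy) {
    if (schedule$cycles == 1L) return(step_end)
    step_start * (step_end / step_start)^((cy - 1) / (schedule$cycles - 1))
  }
  clamp <- function(params) {
    for (j in names(params)) {
      params[j] <- min(max(params[j], bounds[[j]][1]), bounds[[j]][2])
    }
    params
  }
  eval_cl <- function(params, n_sim, seed) {
    model <- set_model_params(base_model, params)
    set.seed(seed)
    probs <- expected_sfs_probs(model, n1, n2, n_sim)
    composite_log_likelihood(observed, probs, n_sim = n_sim)$log_cl
  }

  rep_rows <- vector("list", schedule$replicates)
  best <- list(cl = -Inf, params = NULL)
  for (r in seq_len(schedule$replicates)) {
    params <- vapply(free, function(j) {
      lo <- log(bounds[[j]][1]); hi <- log(bounds[[j]][2])
      exp(stats::runif(1, lo, hi))
    }, numeric(1))
    cur_cl <- -Inf
    for (cy in seq_len(schedule$cycles)) {
      n_sim <- sims_at(cy)
      stp <- step_at(cy)
      seed <- sample.int(.Machine$integer.max, 1L)
      cur_cl <- eval_cl(params, n_sim, seed)
      for (j in sample(free)) {
        for (f in c(stp, 1 / stp)) {
          cand <- clamp(replace(params, j, params[[j]] * f))
          if (cand[[j]] == params[[j]]) next
          cl <- eval_cl(cand, n_sim, seed)
          if (cl > cur_cl) {
            params <- cand
            cur_cl <- cl
          }
        }
      }
      if (verbose) {
        message(sprintf("replicate %d cycle %d: CL = %.2f (%d sims)",
                        r, cy, cur_cl, n_sim))
      }
    }
    # final comparable evaluation at the full budget
    final_cl <- eval_cl(params, schedule$sims_end,
                        sample.int(.Machine$integer.max, 1L))
    rep_rows[[r]] <- data.frame(replicate = r, t(params),
                                log_cl = final_cl)
    if (final_cl > best$cl) best <- list(cl = final_cl, params = params)
  }
  at_bound <- vapply(free, function(j) {
    best$params[[j]] <= bounds[[j]][1] * 1.0001 ||
      best$params[[j]] >= bounds[[j]][2] * 0.9999
  }, logical(1))
  if (any(at_bound)) {
    warning("estimate pinned at a search bound: ",
            paste(free[at_bound], collapse = ", "))
  }
  structure(list(ml_model = set_model_params(base_model, best$params),
                 estimates = best$params, log_cl = best$cl,
                 replicate_results = do.call(rbind, rep_rows),
                 at_bound = at_bound,
                 free = free, bounds = bounds, schedule = schedule,
                 observed = observed, n1 = n1, n2 = n2),
            class = "demographic_fit")
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat("Composite-likelihood demographic fit\n")
  cat(sprintf("  best log-CL = %.2f over %d replicate(s)\n", x$log_cl,
              nrow(x$replicate_results)))
  est <- data.frame(estimate = x$estimates)
  if (!is.null(x$ci95)) {
    est$lo95 <- x$ci95[x$free, "lo"]
    est$hi95 <- x$ci95[x$free, "hi"]
  }
  print(est)
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for a demographic fit
#'
#' Simulates `n_datasets` pseudo-observed joint spectra under the fitted
#' model, each with the same number of sites as the original data, refits
#' each one with the same free parameters, bounds and (typically reduced)
#' schedule, and takes the 2.5% / 97.5% percentiles of the refitted
#' estimates per parameter.  Refit failures are counted and skipped.
#'
#' @param fit a `demographic_fit`.
#' @param n_datasets number of pseudo-observed datasets (150 at full
#'   scale; use fewer for desk work).
#' @param schedule refit schedule; defaults to a lighter single-replicate
#'   version of the fit's own schedule.
#' @return the `fit` with a `ci95` matrix (rows = free parameters,
#'   columns `lo`, `hi`), `bootstrap_estimates`, and `n_failed` attached.
#' @export
parametric_bootstrap_ci <- function(fit, n_datasets = 150,
                                    schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- fit$schedule
    schedule$replicates <- 1L
    schedule$cycles <- max(3L, schedule$cycles %/% 2L)
  }
  n_snps <- sum(fit$observed)
  est <- matrix(NA_real_, n_datasets, length(fit$free),
                dimnames = list(NULL, fit$free))
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    pseudo <- expected_sfs_probs(fit$ml_model, fit$n1, fit$n2, n_snps) *
      n_snps  # one simulated dataset of exactly n_snps sites
    refit <- tryCatch(
      suppressWarnings(
        fit_demography(pseudo, fit$ml_model, fit$free, fit$bounds,
                       schedule = schedule)),
      error = function(e) NULL)
    if (is.null(refit)) {
      n_failed <- n_failed + 1L
    } else {
      est[i, ] <- refit$estimates[fit$free]
    }
  }
  ok <- stats::complete.cases(est)
  ci <- t(apply(est[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  fit$ci95 <- ci
  fit$bootstrap_estimates <- est
  fit$n_failed <- n_failed
  fit
}

#' PCA goodness-of-fit check of a demographic model
#'
#' Simulates joint spectra with parameters drawn uniformly and
#' independently from per-parameter 95% CI ranges, summarises each
#' simulated spectrum as its vector of polymorphic-entry proportions,
#' runs a principal components analysis, and projects the observed
#' spectrum onto PC1-PC2.  The observed data are judged consistent with
#' the model when their projection falls inside the 95% Mahalanobis
#' ellipse of the simulated cloud on PC1-PC2.
#'
#' @param observed a `joint_sfs` of observed counts.
#' @param ci_ranges named list (or 2-column lo/hi matrix) of parameter
#'   ranges to sample; parameters absent from it stay at `base_model`'s
#'   values.
#' @param base_model an `im_model` supplying the non-sampled parameters.
#' @param n_sims number of simulated parameter draws (10,000 at full
#'   scale).
#' @param sites_per_sim unlinked sites per simulated spectrum; defaults
#'   to the observed number of sites.
#' @return a list of class `pca_fit_check`: `observed_pc` (PC1, PC2),
#'   `inside` (logical), `mahalanobis_q` (the quantile of the observed
#'   Mahalanobis distance within the simulated distances), `sim_pc`,
#'   `degenerate` (TRUE when the simulated cloud has no variance).
#' @export
pca_fit_check <- function(observed, ci_ranges, base_model, n_sims = 10000,
                          sites_per_sim = sum(observed)) {
  if (is.matrix(ci_ranges)) {
    ci_ranges <- stats::setNames(
      lapply(seq_len(nrow(ci_ranges)),
             function(i) c(ci_ranges[i, 1L], ci_ranges[i, 2L])),
      rownames(ci_ranges))
  }
  n1 <- (nrow(observed) - 1L) %/% 2L
  n2 <- (ncol(observed) - 1L) %/% 2L
  poly <- polymorphic_mask(dim(observed))
  dim_used <- sum(poly)
  if (n_sims < dim_used) {
    stop("n_sims (", n_sims, ") must be at least the spectrum ",
         "dimensionality (", dim_used, ")")
  }
  sims <- matrix(NA_real_, n_sims, dim_used)
  for (i in seq_len(n_sims)) {
    draw <- vapply(ci_ranges, function(b) stats::runif(1, b[1], b[2]),
                   numeric(1))
    model <- set_model_params(base_model, draw)
    p <- expected_sfs_probs(model, n1, n2, sites_per_sim)
    sims[i, ] <- as.vector(p)[poly]
  }
  obs_vec <- as.vector(unclass(observed))[poly] / sum(observed)
  if (all(apply(sims, 2L, stats::sd) == 0)) {
    return(structure(list(observed_pc = c(NA_real_, NA_real_),
                          inside = NA, mahalanobis_q = NA_real_,
                          sim_pc = NULL, degenerate = TRUE),
                     class = "pca_fit_check"))
  }
  pca <- stats::prcomp(sims, center = TRUE, scale. = FALSE)
  sim_pc <- pca$x[, 1:2, drop = FALSE]
  obs_pc <- drop((obs_vec - pca$center) %*% pca$rotation[, 1:2])
  ctr <- colMeans(sim_pc)
  cov2 <- stats::cov(sim_pc)
  d_sim <- stats::mahalanobis(sim_pc, ctr, cov2)
  d_obs <- stats::mahalanobis(matrix(obs_pc, 1L), ctr, cov2)
  structure(list(observed_pc = obs_pc,
                 inside = d_obs <= stats::quantile(d_sim, 0.95),
                 mahalanobis_q = mean(d_sim <= d_obs),
                 sim_pc = sim_pc, degenerate = FALSE),
            class = "pca_fit_check")
}

#' @export
print.pca_fit_check <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("PCA fit check: degenerate (all simulations identical)\n")
  } else {
    cat(sprintf(
      "PCA fit check: observed at PC1 = %.4g, PC2 = %.4g; %s the 95%% region (Mahalanobis quantile %.3f)\n",
      x$observed_pc[1L], x$observed_pc[2L],
      if (isTRUE(x$inside)) "inside" else "OUTSIDE", x$mahalanobis_q))
  }
  invisible(x)
}
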