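#' Summary-statistics table for marker groups
#'
#' Builds the per-group summary table (one row per dataset / clade /
#' complete-truncated subset): mean pairwise differences (pooled and per
#' population), Tajima's D per population, locus count, the allele-sharing
#' percentages and the mean Weir-Cockerham F_ST.
#'
#' @param groups named list of `genotype_table`s, one per row.
#' @param pops (pop1, pop2) population labels; defaults from the first
#'   table.
#' @return data.frame with one row per group.
#' @export
group_summary_table <- function(groups, pops = NULL) {
  stopifnot(length(groups) >= 1L)
  if (is.null(pops)) pops <- pop_labels(groups[[1L]])
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    D1 <- tryCatch(tajimas_d(x, pops[1L])$D, error = function(e) NA_real_)
    D2 <- tryCatch(tajimas_d(x, pops[2L])$D, error = function(e) NA_real_)
    sh <- sharing_partition(x, pops)
    data.frame(group = g,
               pi_all = mean_pairwise_diff(x),
               pi_pop1 = mean_pairwise_diff(x, pops[1L]),
               pi_pop2 = mean_pairwise_diff(x, pops[2L]),
               D_pop1 = D1, D_pop2 = D2,
               n_loci = n_sites(x),
               pct_private_pop1 = sh$pct_private_pop1,
               pct_private_pop2 = sh$pct_private_pop2,
               pct_fixed = sh$pct_fixed_diff,
               pct_shared = sh$pct_shared,
               mean_fst = weir_cockerham_fst(x)$mean_fst,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# split one MEI table into the All/FL/TR group rows used by the summary
mei_groups <- function(mei, lengths) {
  cls <- classify_complete(mei, lengths)
  groups <- list()
  for (cl in unique(mei$sites$clade)) {
    in_clade <- mei$sites$clade == cl
    groups[[paste0(cl, "_All")]] <- mei[which(in_clade)]
    if (any(in_clade & cls == "COMPLETE")) {
      groups[[paste0(cl, "_FL")]] <- mei[which(in_clade & cls == "COMPLETE")]
    }
    if (any(in_clade & cls == "TRUNCATED")) {
      groups[[paste0(cl, "_TR")]] <- mei[which(in_clade & cls == "TRUNCATED")]
    }
  }
  groups
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages -- synthesize (optional), filter, catalog,
#' stats, fit (optional), neutrality test -- and writes the report bundle
#' as TSV files under `config$out_dir`.  Every stage is a pure function of
#' the inputs and `config$seed`, so identical configurations give
#' byte-identical reports.  A stage failure stops the run with an error
#' naming the stage; outputs of completed stages are retained.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{integer seed (required).}
#'     \item{synth}{optional list: `n_snps`, `families` (data.frame for
#'       [generate_mei_dataset()]), `gamma`, `model`; when present the
#'       inputs are generated here.}
#'     \item{snp_vcf, mei_vcfs, popmap}{input paths (used when `synth` is
#'       absent; `mei_vcfs` is a named character vector, names = family,
#'       optionally with a `clades` attribute-like companion
#'       `mei_clades`).}
#'     \item{filter}{list of [filter_snps()] arguments plus `thin_step`.}
#'     \item{fit}{optional list: `free`, `bounds`, `schedule`,
#'       `base_model` to run [fit_demography()] on the SNP joint SFS, and
#'       optionally `n_bootstrap` for CIs.}
#'     \item{test}{optional list: `ci_ranges`, `base_model`, `n_sims` to
#'       run per-clade neutrality tests of Tajima's D.}
#'   }
#' @return (invisibly) a list with the computed objects and the paths of
#'   every report file written.
#' @export
run_pipeline <- function(config) {
  stopifnot(!is.null(config$out_dir), !is.null(config$seed))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  log_path <- file.path(out, "run_log.txt")
  log_lines <- c(sprintf("linepopgen %s",
                         as.character(utils::packageVersion("linepopgen"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed: %d", config$seed))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))), log_path)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  results <- list()

  # ---- synthesize -------------------------------------------------------
  if (!is.null(config$synth)) {
    stage("synth", {
      sdir <- file.path(out, "input")
      model <- config$synth$model
      if (is.null(model)) model <- anole_im_model()
      snp <- generate_snp_dataset(model,
                                  n_sites = config$synth$n_snps %||% 1000,
                                  dir = sdir)
      fams <- config$synth$families %||% data.frame(
        family = c("CR1AC01", "L2AC09", "RTE-1"),
        clade = c("CR1", "L2", "RTE1"),
        n_loci = c(200L, 150L, 100L))
      mei <- generate_mei_dataset(model, fams,
                                  gamma = config$synth$gamma %||% 0,
                                  dir = sdir)
      config$snp_vcf <- snp$vcf
      config$popmap <- snp$popmap
      config$mei_vcfs <- mei$paths
      config$mei_clades <- stats::setNames(fams$clade, fams$family)
    })
  }

  # ---- filter -----------------------------------------------------------
  snps <- stage("filter", {
    pm <- read_population_map(config$popmap)
    raw <- read_snp_vcf(config$snp_vcf, pm)
    f <- config$filter %||% list()
    flt <- filter_snps(raw,
                       min_dp = f$min_dp %||% 6,
                       min_gq = f$min_gq %||% 20,
                       min_q = f$min_q %||% 20,
                       min_fraction_called = f$min_fraction_called %||% 1)
    if (!is.null(f$thin_step) && f$thin_step > 1) {
      flt <- thin_snps(flt, f$thin_step)
    }
    paths$filtered_snp_vcf <- file.path(out, "snps_filtered.vcf")
    write_vcf(flt, paths$filtered_snp_vcf)
    flt
  })
  results$snps <- snps

  # ---- catalog ----------------------------------------------------------
  mei <- NULL
  lengths <- config$family_lengths %||% default_family_lengths()
  if (!is.null(config$mei_vcfs)) {
    mei <- stage("catalog", {
      pm <- read_population_map(config$popmap)
      clades <- config$mei_clades
      callsets <- lapply(names(config$mei_vcfs), function(fam) {
        read_mei_vcf(config$mei_vcfs[[fam]], pm, family = fam,
                     clade = if (!is.null(clades)) clades[[fam]] else
                       NA_character_)
      })
      m <- merge_mei_callsets(callsets)
      m <- dedup_nearby(m, window_bp = 50)
      paths$clade_summary <- file.path(out, "clade_summary.tsv")
      utils::write.table(clade_summary(m, lengths), paths$clade_summary,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths$family_summary <- file.path(out, "family_summary.tsv")
      utils::write.table(clade_summary(m, lengths, by = "family"),
                         paths$family_summary, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths$individual_counts <- file.path(out, "individual_counts.tsv")
      utils::write.table(per_individual_counts(m, lengths),
                         paths$individual_counts, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths$length_histogram <- file.path(out, "length_histogram.tsv")
      utils::write.table(length_histogram(m), paths$length_histogram,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      m
    })
  }
  results$mei <- mei

  # ---- stats ------------------------------------------------------------
  stage("stats", {
    groups <- list(SNPs = snps)
    if (!is.null(mei)) groups <- c(groups, mei_groups(mei, lengths))
    summary_tab <- group_summary_table(groups)
    paths$summary_stats <- file.path(out, "summary_stats.tsv")
    utils::write.table(summary_tab, paths$summary_stats, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$summary_stats <- summary_tab
    # per-population spectra of the SNP set (report form of the SFS plot)
    for (p in pop_labels(snps)) {
      s <- site_sfs(snps, p, "minor_folded")
      paths[[paste0("sfs_", p)]] <- file.path(out,
                                               paste0("sfs_", p, ".tsv"))
      utils::write.table(
        data.frame(k = 0:s$n, count = s$counts),
        paths[[paste0("sfs_", p)]], sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  })

  # ---- fit --------------------------------------------------------------
  if (!is.null(config$fit)) {
    stage("fit", {
      obs <- joint_sfs(snps)
      fit <- fit_demography(obs,
                            base_model = config$fit$base_model %||%
                              anole_im_model(),
                            free = config$fit$free,
                            bounds = config$fit$bounds,
                            schedule = config$fit$schedule %||%
                              fit_schedule("desk"))
      if (!is.null(config$fit$n_bootstrap)) {
        fit <- parametric_bootstrap_ci(fit, config$fit$n_bootstrap)
      }
      est <- data.frame(parameter = fit$free,
                        estimate = unname(fit$estimates[fit$free]))
      if (!is.null(fit$ci95)) {
        est$lo95 <- fit$ci95[, "lo"]; est$hi95 <- fit$ci95[, "hi"]
      }
      paths$fit <- file.path(out, "demographic_fit.tsv")
      utils::write.table(est, paths$fit, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      results$fit <- fit
    })
  }

  # ---- neutrality test --------------------------------------------------
  if (!is.null(config$test) && !is.null(mei)) {
    stage("test", {
      groups <- list()
      for (cl in unique(mei$sites$clade)) {
        sub <- mei[which(mei$sites$clade == cl)]
        obs_d <- tryCatch(tajimas_d(sub, pop_labels(sub)[1L])$D,
                          error = function(e) NA_real_)
        if (!is.na(obs_d)) {
          groups[[cl]] <- list(observed = obs_d, n_loci = n_sites(sub))
        }
      }
      rep <- neutrality_report(groups,
                               ci_ranges = config$test$ci_ranges %||%
                                 anole_model_ci()[, c("lo", "hi")],
                               base_model = config$test$base_model %||%
                                 anole_im_model(),
                               n_sims = config$test$n_sims %||% 5000)
      paths$neutrality <- file.path(out, "neutrality_tests.tsv")
      utils::write.table(rep, paths$neutrality, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      results$neutrality <- rep
    })
  }

  log_lines <- c(log_lines,
                 sprintf("elapsed: %.1f s", proc.time()[["elapsed"]] - t0),
                 paste("wrote:", unlist(paths)))
  writeLines(log_lines, log_path)
  paths$log <- log_path
  invisible(c(results, list(paths = paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
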