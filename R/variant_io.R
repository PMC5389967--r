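#' Read a multi-sample SNP VCF
#'
#' Parses a VCF 4.2 file (via vcfR) into a [genotype_table()], keeping the
#' per-genotype `DP` and `GQ` FORMAT fields needed by [filter_snps()].
#' Multi-allelic sites are kept at this stage (dosage counts the first ALT
#' allele); [filter_snps()] removes them when `biallelic_only = TRUE`.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param popmap a [population_map()] covering every sample in the file.
#' @return a `genotype_table` of type `"snp"`.
#' @export
read_snp_vcf <- function(path, popmap) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      id = fix$ID,
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      filter = fix$FILTER,
                      stringsAsFactors = FALSE)
  dosage <- gt_to_dosage(vcfR::extract.gt(v, element = "GT"))
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  rownames(dp) <- NULL
  rownames(gq) <- NULL
  genotype_table(sites, dosage, popmap, dp = dp, gq = gq, type = "snp")
}

#' Read a MELT-style MEI VCF
#'
#' Reads one per-family VCF of polymorphic mobile-element insertions.
#' Predicted insertion length is taken from the standard structural-variant
#' `SVLEN` INFO key when present, falling back to a `MEILEN` key; the
#' family and clade labels come from `FAMILY` / `CLADE` INFO keys, with the
#' `family`/`clade` arguments as fallback.  The FILTER column is kept as
#' the call-quality flag (`PASS` = good call).
#'
#' @param path VCF file path.
#' @param popmap a [population_map()].
#' @param family,clade fallback labels when the INFO fields are absent.
#' @return a `genotype_table` of type `"mei"` with `family`, `clade` and
#'   `length` site columns.
#' @export
read_mei_vcf <- function(path, popmap, family = NA_character_,
                         clade = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- fix$INFO
  if (is.null(info)) info <- vcfR::getINFO(v)
  len <- info_field(info, "SVLEN")
  len2 <- info_field(info, "MEILEN")
  len <- ifelse(is.na(len), len2, len)
  fam <- info_field(info, "FAMILY", numeric = FALSE)
  cld <- info_field(info, "CLADE", numeric = FALSE)
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      id = fix$ID,
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      filter = fix$FILTER,
                      family = ifelse(is.na(fam), family, fam),
                      clade = ifelse(is.na(cld), clade, cld),
                      length = abs(as.numeric(len)),
                      stringsAsFactors = FALSE)
  dosage <- gt_to_dosage(vcfR::extract.gt(v, element = "GT"))
  genotype_table(sites, dosage, popmap, type = "mei")
}

# "0/0", "0|1", "./." ... -> 0/1/2/NA alternate-allele dosage
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt),
              dimnames = list(NULL, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  d[clean == "0/0"] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean == "1/1"] <- 2L
  d
}

info_field <- function(info, key, numeric = TRUE) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", regmatches(info, regexpr(pat, info, perl = TRUE)),
                  perl = TRUE)
  if (numeric) suppressWarnings(as.numeric(out)) else out
}

#' Write a genotype table as a plain-text VCF 4.2 file
#'
#' SNP tables emit `GT:DP:GQ` genotypes; MEI tables emit `GT` plus
#' `SVLEN`, `MEILEN`, `FAMILY` and `CLADE` INFO keys so that
#' [read_mei_vcf()] round-trips positions, genotypes and lengths exactly.
#'
#' @param x a `genotype_table`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  s <- x$sites
  n <- nrow(s)
  samples <- colnames(x$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=linepopgen",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Predicted insertion length\">",
           "##INFO=<ID=MEILEN,Number=1,Type=Integer,Description=\"Predicted insertion length (MELT-style)\">",
           "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"LINE family\">",
           "##INFO=<ID=CLADE,Number=1,Type=String,Description=\"LINE clade\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- matrix(".", n, length(samples))
  gt[x$dosage == 0L] <- "0/0"
  gt[x$dosage == 1L] <- "0/1"
  gt[x$dosage == 2L] <- "1/1"
  gt[is.na(x$dosage)] <- "./."
  if (x$type == "snp" && !is.null(x$dp) && !is.null(x$gq)) {
    fmt <- "GT:DP:GQ"
    cell <- matrix(paste(gt, ifelse(is.na(x$dp), ".", x$dp),
                         ifelse(is.na(x$gq), ".", x$gq), sep = ":"),
                   n, length(samples))
    info <- rep(".", n)
  } else {
    fmt <- "GT"
    cell <- gt
    info <- rep(".", n)
    if (x$type == "mei") {
      info <- paste0("SVLEN=", as.integer(s$length),
                     ";MEILEN=", as.integer(s$length),
                     ";FAMILY=", s$family, ";CLADE=", s$clade)
    }
  }
  body <- paste(s$chrom, s$pos,
                if (!is.null(s$id)) ifelse(is.na(s$id), ".", s$id) else ".",
                s$ref, s$alt,
                ifelse(is.na(s$qual), ".", s$qual),
                if (!is.null(s$filter)) ifelse(is.na(s$filter), ".", s$filter) else "PASS",
                info, fmt,
                apply(cell, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter SNP sites on quality, depth, completeness and allele structure
#'
#' Applies the site-wise quality recipe used for the anole SNP set: every
#' genotype at a retained site must reach the depth and genotype-quality
#' floors, the site quality must reach `min_q`, indels and non-biallelic
#' records are removed, and (by default) no missing genotypes are
#' tolerated.  A failing genotype fails the whole site.  Sites lacking the
#' depth/quality annotations needed to evaluate the thresholds are dropped
#' with a message rather than aborting the run.
#'
#' @param x a `genotype_table` of type `"snp"` with `dp`/`gq` matrices.
#' @param min_dp minimum per-genotype sequencing depth (default 6).
#' @param min_gq minimum per-genotype Phred quality (default 20).
#' @param min_q minimum site Phred quality (default 20).
#' @param min_fraction_called minimum fraction of samples with a called
#'   genotype; the default 1 means no missing genotypes are tolerated.
#' @param biallelic_only drop sites whose ALT has more than one allele.
#' @param remove_indels drop records whose REF or ALT is longer than 1 bp.
#' @return the filtered `genotype_table`.
#' @export
filter_snps <- function(x, min_dp = 6, min_gq = 20, min_q = 20,
                        min_fraction_called = 1, biallelic_only = TRUE,
                        remove_indels = TRUE) {
  s <- x$sites
  n <- nrow(s)
  keep <- rep(TRUE, n)
  if (remove_indels) {
    alt_alleles <- strsplit(s$alt, ",", fixed = TRUE)
    is_indel <- nchar(s$ref) != 1L |
      vapply(alt_alleles, function(a) any(nchar(a) != 1L), logical(1))
    keep <- keep & !is_indel
  }
  if (biallelic_only) keep <- keep & !grepl(",", s$alt)
  if (min_q > 0) keep <- keep & !is.na(s$qual) & s$qual >= min_q
  called <- !is.na(x$dosage)
  frac_called <- rowMeans(called)
  keep <- keep & frac_called >= min_fraction_called
  if (min_dp > 0 || min_gq > 0) {
    if (is.null(x$dp) || is.null(x$gq)) {
      message("depth/quality annotations absent: dropping all sites that ",
              "cannot be evaluated")
      keep <- keep & FALSE
    } else {
      # annotation required wherever a genotype is called
      dp_na <- called & is.na(x$dp)
      gq_na <- called & is.na(x$gq)
      unannotated <- rowSums(dp_na | gq_na) > 0
      if (any(unannotated & keep)) {
        message(sum(unannotated & keep),
                " site(s) dropped for missing DP/GQ annotations")
      }
      dp_ok <- !called | (!is.na(x$dp) & x$dp >= min_dp)
      gq_ok <- !called | (!is.na(x$gq) & x$gq >= min_gq)
      keep <- keep & !unannotated & rowSums(!dp_ok) == 0 &
        rowSums(!gq_ok) == 0
    }
  }
  x[which(keep)]
}

#' Thin sites to every k-th record
#'
#' Keeps the records at ordinal positions 1, 1 + `step`, 1 + 2`step`, ...
#' in (chrom, pos) sorted order, the standard device for limiting linkage
#' disequilibrium among retained SNPs.  Genome-wide by default; set
#' `per_chromosome = TRUE` to restart the counter on each chromosome.
#'
#' @param x a `genotype_table`.
#' @param step positive integer sampling interval (e.g. 1000).
#' @param per_chromosome restart the ordinal counter per chromosome.
#' @return the thinned `genotype_table`.
#' @export
thin_snps <- function(x, step, per_chromosome = FALSE) {
  if (!is.numeric(step) || length(step) != 1L || step < 1 ||
      step != round(step)) {
    stop("step must be a single integer >= 1")
  }
  n <- n_sites(x)
  if (n == 0L) return(x)
  if (per_chromosome) {
    ord <- unlist(lapply(split(seq_len(n), x$sites$chrom), function(i) {
      i[seq(1L, length(i), by = step)]
    }), use.names = FALSE)
    x[sort(ord)]
  } else {
    x[seq(1L, n, by = step)]
  }
}

#' Merge per-family MEI callsets into one table
#'
#' Takes the union of loci across family callsets.  With
#' `require_full_coverage = TRUE` (the default), loci with any missing
#' genotype or a non-PASS call-quality flag are removed, mirroring the
#' post-calling cleanup of combining per-family VCFs and discarding loci
#' without coverage in all samples or with low-quality calls.
#'
#' @param callsets list of `genotype_table`s of type `"mei"`, one per
#'   family, sharing one sample set.
#' @param require_full_coverage drop loci with missing genotypes or
#'   failing quality flags.
#' @return a merged `genotype_table`.
#' @export
merge_mei_callsets <- function(callsets, require_full_coverage = TRUE) {
  stopifnot(length(callsets) >= 1L)
  ref_samples <- colnames(callsets[[1L]]$dosage)
  for (i in seq_along(callsets)) {
    if (!setequal(colnames(callsets[[i]]$dosage), ref_samples)) {
      stop("callset ", i, " (",
           paste(utils::head(unique(callsets[[i]]$sites$family), 1L)),
           ") has a different sample set")
    }
  }
  sites <- do.call(rbind, lapply(callsets, function(cs) cs$sites))
  dosage <- do.call(rbind, lapply(callsets, function(cs) {
    cs$dosage[, ref_samples, drop = FALSE]
  }))
  out <- genotype_table(sites, dosage, callsets[[1L]]$popmap, type = "mei")
  if (require_full_coverage) {
    full <- rowSums(is.na(out$dosage)) == 0L
    pass <- if (!is.null(out$sites$filter)) {
      is.na(out$sites$filter) | out$sites$filter %in% c("PASS", ".")
    } else TRUE
    out <- out[which(full & pass)]
  }
  out
}

#' Collapse nearby duplicate MEI calls, keeping the longest
#'
#' Clusters are built by single linkage: records on one chromosome whose
#' positions chain together within `window_bp` of a neighbour form one
#' cluster, and only the record with the maximal predicted length survives
#' (ties broken by lowest position).  This resolves the same physical
#' insertion being called against several family consensus sequences.
#'
#' @param x a `genotype_table` of type `"mei"` with a `length` column.
#' @param window_bp clustering window in bp (default 50).
#' @return the deduplicated `genotype_table`.
#' @export
dedup_nearby <- function(x, window_bp = 50) {
  n <- n_sites(x)
  if (n <= 1L) return(x)
  s <- x$sites
  # sites are sorted by (chrom, pos); chain neighbours within the window
  new_cluster <- c(TRUE, s$chrom[-1L] != s$chrom[-n] |
                     s$pos[-1L] - s$pos[-n] > window_bp)
  cluster <- cumsum(new_cluster)
  keep <- vapply(split(seq_len(n), cluster), function(i) {
    i[order(-s$length[i], s$pos[i])][1L]
  }, integer(1))
  x[sort(unname(keep))]
}
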