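# Allele harmonisation and variant quality-control filters.

is_palindromic <- function(ea, oa) {
  paste0(ea, oa) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonise GWAS summary statistics to a genotype panel
#'
#' Matches summary-statistic records to genotype variants on (chromosome,
#' position) and aligns the effect direction to the allele counted in the
#' dosage matrix: when the summary-statistic effect allele equals the
#' genotype's other allele, the record's `beta` is negated and `eaf`
#' complemented. Strand-ambiguous (palindromic A/T, C/G) variants whose
#' effect-allele frequency is too close to 0.5 to resolve strand are
#' dropped. Records without a position or allele match are excluded and
#' logged.
#'
#' @param stats Summary-statistics tibble (`chrom`, `pos`, `ea`, `oa`,
#'   `beta`, `se`, `p`, `eaf`).
#' @param geno A `geno_matrix`.
#' @param ambiguity_window Palindromic variants with
#'   `|eaf - 0.5| < ambiguity_window` are dropped (default 0.08).
#' @return List with `stats` (aligned records, effect allele equal to the
#'   genotype's counted allele) and `report` (a `harmonization_report`
#'   with counts and a per-variant action log).
#' @export
harmonize <- function(stats, geno, ambiguity_window = 0.08) {
  if (nrow(stats) == 0 || nrow(geno$variants) == 0) {
    stop_pgs("Both summary statistics and genotypes must be non-empty.",
             "pgsrisk_validation")
  }
  if (anyDuplicated(position_key(stats))) {
    stop_pgs("Duplicate variant keys in summary statistics.",
             "pgsrisk_validation")
  }
  gv <- geno$variants
  match_idx <- match(position_key(stats), position_key(gv))

  action <- character(nrow(stats))
  beta <- stats$beta
  eaf <- stats$eaf
  ea <- stats$ea
  oa <- stats$oa
  for (i in seq_len(nrow(stats))) {
    j <- match_idx[i]
    if (is.na(j)) {
      action[i] <- "unmatched"
      next
    }
    same <- stats$ea[i] == gv$ea[j] && stats$oa[i] == gv$oa[j]
    flipped <- stats$ea[i] == gv$oa[j] && stats$oa[i] == gv$ea[j]
    if (!same && !flipped) {
      action[i] <- "unmatched"
      next
    }
    if (is_palindromic(stats$ea[i], stats$oa[i]) &&
        abs(stats$eaf[i] - 0.5) < ambiguity_window) {
      action[i] <- "drop_ambiguous"
      next
    }
    if (flipped) {
      beta[i] <- -beta[i]
      eaf[i] <- 1 - eaf[i]
      ea[i] <- gv$ea[j]
      oa[i] <- gv$oa[j]
      action[i] <- "flip"
    } else {
      action[i] <- "keep"
    }
  }
  kept <- action %in% c("keep", "flip")
  aligned <- stats[kept, , drop = FALSE]
  aligned$beta <- beta[kept]
  aligned$eaf <- eaf[kept]
  aligned$ea <- ea[kept]
  aligned$oa <- oa[kept]
  if (nrow(aligned) == 0) {
    stop_pgs("No summary-statistic variant matched the genotype panel.",
             "pgsrisk_empty_intersection")
  }
  report <- structure(list(
    n_matched = sum(kept),
    n_allele_flipped = sum(action == "flip"),
    n_strand_ambiguous_dropped = sum(action == "drop_ambiguous"),
    n_unmatched = sum(action == "unmatched"),
    log = tibble(chrom = stats$chrom, pos = stats$pos,
                 ea = stats$ea, oa = stats$oa, action = action)
  ), class = "harmonization_report")
  list(stats = aligned, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report> matched:", x$n_matched,
      "(flipped:", x$n_allele_flipped, ")",
      "ambiguous dropped:", x$n_strand_ambiguous_dropped,
      "unmatched:", x$n_unmatched, "\n")
  invisible(x)
}

#' Filter genotype variants on MAF and imputation quality
#'
#' Retains exactly the variants with minor allele frequency
#' `>= maf_min` and info score `>= info_min`; MAF is computed as
#' `min(eaf, 1 - eaf)`. Defaults reproduce the conventional post-imputation
#' exclusion of variants with info below 0.5 or MAF below 0.01.
#'
#' @param geno A `geno_matrix`.
#' @param maf_min Minimum minor allele frequency (in `[0, 0.5]`).
#' @param info_min Minimum imputation info score (in `[0, 1]`).
#' @return A filtered `geno_matrix` (possibly with zero variants).
#' @export
qc_filter <- function(geno, maf_min = 0.01, info_min = 0.5) {
  if (maf_min < 0 || maf_min > 0.5 || info_min < 0 || info_min > 1) {
    stop_pgs("Thresholds must satisfy maf_min in [0, 0.5], info_min in [0, 1].",
             "pgsrisk_invalid_config")
  }
  v <- geno$variants
  keep <- pmin(v$eaf, 1 - v$eaf) >= maf_min & v$info >= info_min
  structure(list(
    dosages = geno$dosages[, keep, drop = FALSE],
    sample_ids = geno$sample_ids,
    variants = v[keep, , drop = FALSE]
  ), class = "geno_matrix")
}
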