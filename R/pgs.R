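# Polygenic score construction: pruning-and-thresholding variant
# selection, weighted allele sums, standardisation, PC residualisation.

#' Select independent significant variants by pruning and thresholding
#'
#' Greedy selection in ascending p-value order among variants with
#' `p < p_threshold`: a candidate is rejected when it lies within
#' `window_bp` of an already-selected variant on the same chromosome and
#' its squared dosage correlation with that variant exceeds `r2_max`.
#' Ties in p-value are broken by genomic position, then allele order, so
#' the selection is invariant to the input record order.
#'
#' @param stats Harmonised summary-statistics tibble.
#' @param geno A `geno_matrix` providing dosages for the LD computation.
#' @param p_threshold Significance threshold (default genome-wide, 5e-8).
#' @param window_bp Pruning window in base pairs (default 500 kb).
#' @param r2_max Maximum allowed squared dosage correlation (default 0.1).
#' @return The selected subset of `stats`, in selection order.
#' @export
select_variants_pt <- function(stats, geno, p_threshold = 5e-8,
                               window_bp = 5e5, r2_max = 0.1) {
  if (p_threshold <= 0 || p_threshold > 1 || window_bp < 0 ||
      r2_max < 0 || r2_max > 1) {
    stop_pgs("Invalid pruning-and-thresholding thresholds.",
             "pgsrisk_invalid_config")
  }
  cand <- stats %>%
    filter(.data$p < p_threshold) %>%
    arrange(.data$p, .data$chrom, .data$pos, .data$ea, .data$oa)
  if (nrow(cand) == 0) return(cand)
  gpos <- match(position_key(cand), position_key(geno$variants))
  if (anyNA(gpos)) {
    stop_pgs("Genotypes unavailable for some candidate variants.",
             "pgsrisk_validation")
  }
  selected <- integer(0)
  for (i in seq_len(nrow(cand))) {
    near <- selected[cand$chrom[selected] == cand$chrom[i] &
                       abs(cand$pos[selected] - cand$pos[i]) <= window_bp]
    reject <- FALSE
    for (j in near) {
      r <- suppressWarnings(
        stats::cor(geno$dosages[, gpos[i]], geno$dosages[, gpos[j]],
                   use = "complete.obs")
      )
      # zero-variance dosages give NA correlation: treated as independent
      if (!is.na(r) && r^2 > r2_max) {
        reject <- TRUE
        break
      }
    }
    if (!reject) selected <- c(selected, i)
  }
  cand[selected, , drop = FALSE]
}

#' Compute a raw polygenic score as a weighted allele sum
#'
#' For each individual, sums dosage times log odds ratio over the weight
#' variants: `raw_i = sum_v dosage_iv * beta_v`. Weights must already be
#' harmonised to the genotype panel (identical variant keys including
#' allele orientation); any missing dosage is imputed as twice the
#' genotype effect-allele frequency and logged.
#'
#' @param geno A `geno_matrix`.
#' @param weights Aligned summary-statistics tibble (subset of the panel).
#' @param weight_source Label recorded on the resulting score.
#' @return A polygenic-score tibble (`id`, `raw`) with attributes
#'   `n_variants_used` and `weight_source`.
#' @export
compute_ps <- function(geno, weights, weight_source = "external") {
  idx <- match(variant_key(weights), variant_key(geno$variants))
  if (anyNA(idx)) {
    stop_pgs(paste0(sum(is.na(idx)), " weight variant(s) are not harmonised",
                    " to the genotype panel (run harmonize() first)."),
             "pgsrisk_contract_violation")
  }
  dos <- geno$dosages[, idx, drop = FALSE]
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    eaf <- geno$variants$eaf[idx]
    for (k in seq_along(idx)) {
      miss <- is.na(dos[, k])
      if (any(miss)) dos[miss, k] <- 2 * eaf[k]
    }
    inform(paste0("compute_ps: ", n_missing,
                  " missing dosage value(s) imputed as 2*EAF."))
  }
  raw <- as.vector(dos %*% weights$beta)
  new_ps(tibble(id = geno$sample_ids, raw = raw),
         n_variants_used = nrow(weights), weight_source = weight_source)
}

new_ps <- function(df, n_variants_used, weight_source) {
  structure(as_tibble(df),
            n_variants_used = n_variants_used,
            weight_source = weight_source,
            class = c("polygenic_score", class(as_tibble(df))))
}

#' @export
print.polygenic_score <- function(x, ...) {
  cat("<polygenic_score> ", nrow(x), " individuals, ",
      attr(x, "n_variants_used"), " variants, source: ",
      attr(x, "weight_source"), "\n", sep = "")
  NextMethod()
}

#' Standardise a polygenic score over a reference population
#'
#' Adds a `standardized` column: `(raw - mean_ref) / sd_ref`, with mean
#' and SD computed over the reference individuals. Over the reference set
#' itself the standardised score has mean 0 and SD 1; hazard ratios for
#' the score are then expressed per SD. Scoring a subcohort against a
#' wider reference leaves the subcohort SD unequal to 1 in general.
#'
#' @param ps A polygenic-score tibble with a `raw` column.
#' @param reference_ids Ids defining the standardisation population
#'   (default: everyone in `ps`).
#' @return The score tibble with a `standardized` column.
#' @export
standardize_ps <- function(ps, reference_ids = ps$id) {
  ref <- ps$raw[ps$id %in% reference_ids]
  if (length(ref) < 2) {
    stop_pgs("Reference set must contain at least 2 individuals.",
             "pgsrisk_validation")
  }
  s <- sd(ref)
  if (!is.finite(s) || s == 0) {
    stop_pgs("Polygenic score has zero variance over the reference set.",
             "pgsrisk_degenerate_score")
  }
  ps$standardized <- (ps$raw - mean(ref)) / s
  ps
}

#' Residualise a polygenic score on covariates
#'
#' Regresses the standardised score on the covariate matrix (plus an
#' intercept) by least squares, and returns the re-standardised residual.
#' Used to adjust the score for genetic principal components.
#'
#' @param ps A standardised polygenic-score tibble.
#' @param covariates Numeric matrix (rows aligned with `ps`), full column
#'   rank.
#' @return The score tibble with `raw` and `standardized` replaced by the
#'   re-standardised residual score.
#' @export
residualize_ps <- function(ps, covariates) {
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(ps)) {
    stop_pgs("Covariate rows must align with the score.", "pgsrisk_validation")
  }
  X <- cbind(1, covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop_pgs("Covariate matrix is rank deficient (collinear columns).",
             "pgsrisk_collinearity")
  }
  if (is.null(ps$standardized)) ps <- standardize_ps(ps)
  res <- ps$standardized - X %*% qr.coef(qr_x, ps$standardized)
  s <- sd(res)
  if (!is.finite(s) || s < 1e-10) {
    stop_pgs("Score is degenerate after residualisation (fully explained).",
             "pgsrisk_degenerate_score")
  }
  out <- ps
  out$raw <- as.vector(res)
  out$standardized <- as.vector((res - mean(res)) / s)
  attr(out, "weight_source") <- paste0(attr(ps, "weight_source"),
                                       "+residualized")
  out
}
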