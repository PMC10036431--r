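# Cross-validated population-specific polygenic scores: out-of-fold
# weights (tenfold by default) and out-of-half variant selection
# (twofold by default), both guarding against overfitting to the target
# population.

cv_fold_assignment <- function(n, k, seed) {
  with_rng_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# Per-variant single-SNP association estimates on a subset of samples.
# `model = "logistic"` regresses the event indicator on dosage (weights =
# log OR, matching the convention of external GWAS weights);
# `model = "cox"` uses an unadjusted per-variant Cox log HR.
single_variant_assoc <- function(geno, outcome, time = NULL, rows,
                                 model = c("logistic", "cox")) {
  model <- match.arg(model)
  nv <- ncol(geno$dosages)
  beta <- se <- p <- numeric(nv)
  y <- outcome[rows]
  if (all(y == 0) || all(y == 1)) {
    stop_pgs("Fold without both events and non-events; reduce k.",
             "pgsrisk_fold_degeneracy")
  }
  for (v in seq_len(nv)) {
    d <- geno$dosages[rows, v]
    if (model == "logistic") {
      fit <- suppressWarnings(
        glm.fit(cbind(1, d), y, family = binomial())
      )
      cf <- fit$coefficients[2]
      if (is.na(cf)) {  # monomorphic in this subset
        beta[v] <- 0; se[v] <- Inf; p[v] <- 1
      } else {
        vc <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
        s <- if (is.null(vc)) NA_real_ else sqrt(vc[2, 2])
        beta[v] <- cf
        se[v] <- s
        p[v] <- if (is.na(s)) 1 else 2 * pnorm(-abs(cf / s))
      }
    } else {
      fit <- fast_cox1(time[rows], y, d)
      beta[v] <- fit["beta"]
      se[v] <- fit["se"]
      p[v] <- 2 * pnorm(-abs(fit["beta"] / fit["se"]))
    }
  }
  tibble(variant = variant_key(geno$variants), beta = beta, se = se, p = p)
}

#' Cross-validated population-specific weights for a fixed variant set
#'
#' Partitions the samples into `k` folds; for each fold, per-variant
#' weights (single-variant log odds ratios of the event indicator on
#' dosage, or per-variant Cox log hazard ratios) are estimated on the
#' other `k - 1` folds and applied only to the held-out fold. The
#' concatenated out-of-fold raw scores are returned, so no individual's
#' score uses weights estimated on their own fold.
#'
#' @param geno A `geno_matrix` restricted (or restrictable) to the chosen
#'   variant set.
#' @param phenotype Cohort tibble covering the genotyped samples (`id`,
#'   `followup_time`, `event`).
#' @param variants Optional summary-statistics tibble naming the variants
#'   to score (default: all panel variants).
#' @param k Number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed Integer seed fixing the fold assignment.
#' @param model Per-variant association model, `"logistic"` (default) or
#'   `"cox"`.
#' @return A polygenic-score tibble (`id`, `raw`) with attributes `folds`
#'   (per-person fold labels) and `fold_weights` (per-fold weight vectors)
#'   for fold bookkeeping.
#' @export
cv_weight_ps <- function(geno, phenotype, variants = NULL, k = 10, seed = 1L,
                         model = c("logistic", "cox")) {
  model <- match.arg(model)
  if (k < 2) stop_pgs("`k` must be at least 2.", "pgsrisk_invalid_config")
  if (!is.null(variants)) {
    idx <- match(variant_key(variants), variant_key(geno$variants))
    if (anyNA(idx)) {
      stop_pgs("Some requested variants are absent from the panel.",
               "pgsrisk_validation")
    }
    geno <- structure(list(dosages = geno$dosages[, idx, drop = FALSE],
                           sample_ids = geno$sample_ids,
                           variants = geno$variants[idx, , drop = FALSE]),
                      class = "geno_matrix")
  }
  ph <- phenotype[match(geno$sample_ids, phenotype$id), ]
  if (anyNA(ph$id)) {
    stop_pgs("Phenotype table does not cover all genotyped samples.",
             "pgsrisk_validation")
  }
  n <- length(geno$sample_ids)
  folds <- cv_fold_assignment(n, k, seed)
  raw <- numeric(n)
  fold_weights <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(folds != f)
    w <- single_variant_assoc(geno, ph$event, ph$followup_time, train, model)
    fold_weights[[f]] <- w$beta
    test <- which(folds == f)
    raw[test] <- as.vector(geno$dosages[test, , drop = FALSE] %*% w$beta)
  }
  out <- new_ps(tibble(id = geno$sample_ids, raw = raw),
                n_variants_used = ncol(geno$dosages),
                weight_source = "CV-weights")
  attr(out, "folds") <- folds
  attr(out, "fold_weights") <- fold_weights
  out
}

#' Cross-validated population-specific variant selection and weights
#'
#' Twofold analogue of deriving a population-specific score: within each
#' half of the samples, the `n_select` variants with the smallest
#' single-variant association p-values are selected and weighted from
#' that half, then used to score the *other* half. With
#' `n_select = n_variants` the selection is vacuous and the result equals
#' [cv_weight_ps()] with `k = 2` on the same fold assignment.
#'
#' @inheritParams cv_weight_ps
#' @param n_select Number of variants to select per half (default 287).
#' @param k Number of folds (default 2).
#' @return A polygenic-score tibble with attributes `folds` and
#'   `selected` (list of per-fold selected variant keys).
#' @export
cv_variant_ps <- function(geno, phenotype, n_select = 287, k = 2, seed = 1L,
                          model = c("logistic", "cox")) {
  model <- match.arg(model)
  if (n_select > ncol(geno$dosages)) {
    stop_pgs("`n_select` exceeds the number of panel variants.",
             "pgsrisk_invalid_config")
  }
  ph <- phenotype[match(geno$sample_ids, phenotype$id), ]
  if (anyNA(ph$id)) {
    stop_pgs("Phenotype table does not cover all genotyped samples.",
             "pgsrisk_validation")
  }
  n <- length(geno$sample_ids)
  folds <- cv_fold_assignment(n, k, seed)
  raw <- numeric(n)
  selected <- vector("list", k)
  vkey <- variant_key(geno$variants)
  for (f in seq_len(k)) {
    train <- which(folds != f)
    w <- single_variant_assoc(geno, ph$event, ph$followup_time, train, model)
    ord <- order(w$p, geno$variants$chrom, geno$variants$pos,
                 geno$variants$ea, geno$variants$oa)
    top <- ord[seq_len(n_select)]
    selected[[f]] <- vkey[top]
    test <- which(folds == f)
    raw[test] <- as.vector(
      geno$dosages[test, top, drop = FALSE] %*% w$beta[top]
    )
  }
  out <- new_ps(tibble(id = geno$sample_ids, raw = raw),
                n_variants_used = n_select,
                weight_source = "CV-variants")
  attr(out, "folds") <- folds
  attr(out, "selected") <- selected
  out
}
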