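# Readers and writers for the formats the pipeline touches: dosage
# matrices (TSV and VCF with a DS FORMAT field), GWAS summary statistics
# (tab-delimited CHR POS EA OA BETA SE P EAF), phenotype CSVs, polygenic
# score CSVs, and YAML simulation configurations. Readers validate and
# reject malformed input rather than silently coercing it.

#' Write a genotype matrix as a tab-delimited dosage file
#'
#' One row per variant: `CHROM POS EA OA EAF INFO` followed by one dosage
#' column per sample. Values round-trip losslessly through
#' [read_dosages()].
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  v <- geno$variants
  # doubles are written with 17 significant digits so the shortest
  # round-trip representation reproduces them bit-exactly on re-read
  fmt <- function(x) sub("^\\s+", "", formatC(x, digits = 17, format = "g"))
  dos <- as.data.frame(apply(t(geno$dosages), 2, fmt))
  df <- dplyr::bind_cols(
    tibble(CHROM = v$chrom, POS = v$pos, EA = v$ea, OA = v$oa,
           EAF = fmt(v$eaf), INFO = fmt(v$info)),
    as_tibble(setNames(dos, geno$sample_ids))
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a genotype matrix as a VCF with dosage genotypes
#'
#' Minimal VCF v4.2: `REF` is the other allele, `ALT` the counted effect
#' allele, per-variant `AF` (effect-allele frequency) and `R2`
#' (imputation info) in the INFO column, and per-sample dosages in the
#' `DS` FORMAT field.
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(geno, path) {
  v <- geno$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Effect allele frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], ".", v$oa[i], v$ea[i], ".", "PASS",
            sprintf("AF=%s;R2=%s", format(v$eaf[i], digits = 15),
                    format(v$info[i], digits = 15)),
            "DS", format(geno$dosages[, i], digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Reads either the package's tab-delimited dosage dialect (see
#' [write_dosage_tsv()]) or a VCF v4.2 with a `DS` FORMAT field. VCF
#' records without `DS` are converted from hard `GT` genotypes (counting
#' ALT alleles) when `convert_gt = TRUE`, and rejected otherwise. The
#' counted (effect) allele is the VCF ALT allele; positions are 1-based.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`.
#' @param convert_gt Convert hard genotypes to dosages when `DS` is
#'   absent (default `TRUE`).
#' @param multiallelic `"error"` (default) or `"drop"` for records with
#'   more than one ALT allele.
#' @return A `geno_matrix`.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"), convert_gt = TRUE,
                         multiallelic = c("error", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) {
    stop_pgs(paste0("File not found: ", path), "pgsrisk_format")
  }
  if (format == "tsv") {
    # columns are read as text and converted with strtod so that the
    # 17-digit representations written by write_dosage_tsv parse exactly
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    fixed <- c("CHROM", "POS", "EA", "OA", "EAF", "INFO")
    if (!all(fixed == names(df)[seq_along(fixed)])) {
      stop_pgs(paste0("Malformed dosage header in ", path,
                      " (line 1): expected columns ",
                      paste(fixed, collapse = " ")), "pgsrisk_format")
    }
    df$CHROM <- as.integer(df$CHROM)
    df$POS <- as.integer(df$POS)
    df$EAF <- as.numeric(df$EAF)
    df$INFO <- as.numeric(df$INFO)
    sample_ids <- names(df)[-seq_along(fixed)]
    dos <- matrix(unlist(lapply(df[sample_ids], as.numeric), use.names = FALSE),
                  nrow = length(sample_ids), ncol = nrow(df), byrow = TRUE)
    geno_matrix(
      dosages = dos, sample_ids = sample_ids,
      variants = tibble(chrom = df$CHROM, pos = df$POS, ea = df$EA,
                        oa = df$OA, eaf = df$EAF, info = df$INFO)
    )
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop_pgs("Package 'vcfR' is required to read VCF files.",
               "pgsrisk_format")
    }
    vcf <- tryCatch(
      vcfR::read.vcfR(path, verbose = FALSE),
      error = function(e) {
        stop_pgs(paste0("Malformed VCF ", path, ": ", conditionMessage(e)),
                 "pgsrisk_format")
      }
    )
    fix <- vcfR::getFIX(vcf)
    fix <- matrix(fix, ncol = 7,
                  dimnames = list(NULL, colnames(fix) %||%
                                    c("CHROM", "POS", "ID", "REF", "ALT",
                                      "QUAL", "FILTER")))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      if (multiallelic == "error") {
        stop_pgs(sprintf("%d multi-allelic record(s) in %s; use multiallelic = \"drop\".",
                         sum(multi), path), "pgsrisk_format")
      }
      vcf <- vcf[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    if (is.null(fmt) || all(is.na(fmt))) {
      if (!convert_gt) {
        stop_pgs("VCF has no DS dosages and GT conversion is disabled.",
                 "pgsrisk_format")
      }
      gt <- vcfR::extract.gt(vcf, element = "GT")
      if (is.null(gt) || all(is.na(gt))) {
        stop_pgs("VCF records carry neither DS nor GT fields.",
                 "pgsrisk_format")
      }
      fmt <- apply(gt, c(1, 2), function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
      })
    }
    info_field <- function(key) {
      x <- vcfR::extract.info(vcf, element = key, as.numeric = TRUE)
      if (is.null(x)) rep(NA_real_, nrow(fix)) else x
    }
    eaf <- info_field("AF")
    dos <- t(fmt)
    if (anyNA(eaf)) {
      eaf_obs <- colMeans(dos, na.rm = TRUE) / 2
      eaf[is.na(eaf)] <- eaf_obs[is.na(eaf)]
    }
    r2 <- info_field("R2")
    r2[is.na(r2)] <- 1
    geno_matrix(
      dosages = dos,
      sample_ids = colnames(fmt),
      variants = tibble(
        chrom = as.integer(fix[, "CHROM"]),
        pos = as.integer(fix[, "POS"]),
        ea = fix[, "ALT"], oa = fix[, "REF"],
        eaf = eaf, info = r2
      )
    )
  }
}

#' Read GWAS summary statistics
#'
#' Tab-delimited dialect `CHR POS EA OA BETA SE P EAF` (1-based
#' positions). An `OR` column in place of `BETA` is log-transformed with
#' a notice; p-values of exactly zero are clamped to the smallest
#' positive double with a warning; duplicate variant keys are rejected.
#'
#' @param path Input path.
#' @return Summary-statistics tibble (`chrom`, `pos`, `ea`, `oa`, `beta`,
#'   `se`, `p`, `eaf`).
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop_pgs(paste0("File not found: ", path), "pgsrisk_format")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("CHR", "POS", "EA", "OA", "SE", "P", "EAF")
  missing <- setdiff(required, names(df))
  has_beta <- "BETA" %in% names(df)
  has_or <- "OR" %in% names(df)
  if (!has_beta && !has_or) missing <- c(missing, "BETA (or OR)")
  if (length(missing) > 0) {
    stop_pgs(paste0("Summary statistics ", path, " lack required column(s): ",
                    paste(missing, collapse = ", ")), "pgsrisk_format")
  }
  beta <- if (has_beta) df$BETA else {
    inform("OR column detected; using log(OR) as the effect size.")
    log(df$OR)
  }
  p <- df$P
  if (any(p == 0)) {
    warn(sprintf("%d p-value(s) of 0 clamped to the smallest positive double.",
                 sum(p == 0)))
    p[p == 0] <- .Machine$double.xmin
  }
  if (any(p < 0 | p > 1)) {
    stop_pgs("P column contains values outside (0, 1].", "pgsrisk_format")
  }
  out <- tibble(chrom = df$CHR, pos = df$POS, ea = df$EA, oa = df$OA,
                beta = beta, se = df$SE, p = p, eaf = df$EAF)
  if (anyDuplicated(paste(out$chrom, out$pos, out$ea, out$oa))) {
    stop_pgs("Duplicate variant rows in summary statistics.",
             "pgsrisk_validation")
  }
  out
}

#' Write summary statistics in the package dialect
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(
    tibble(CHR = stats$chrom, POS = stats$pos, EA = stats$ea, OA = stats$oa,
           BETA = stats$beta, SE = stats$se, P = stats$p, EAF = stats$eaf),
    path
  )
  invisible(path)
}

#' Read a phenotype / cohort table from CSV
#'
#' @param path CSV with at least `id`, `cohort`, `followup_time`, `event`.
#' @return Cohort tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "cohort", "followup_time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_pgs(paste0("Phenotype file lacks column(s): ",
                    paste(missing, collapse = ", ")), "pgsrisk_format")
  }
  if (any(df$followup_time <= 0) || !all(df$event %in% c(0, 1))) {
    stop_pgs("followup_time must be positive and event must be 0/1.",
             "pgsrisk_validation")
  }
  df
}

#' Write a cohort table to CSV
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Write a polygenic score to CSV (id, raw, standardized)
#' @param ps Polygenic-score tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ps_csv <- function(ps, path) {
  readr::write_csv(
    dplyr::select(as_tibble(ps), dplyr::any_of(c("id", "raw", "standardized"))),
    path
  )
  invisible(path)
}

#' Write a harmonisation report as JSON
#' @param report A `harmonization_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(report, path) {
  jsonlite::write_json(
    list(n_matched = report$n_matched,
         n_allele_flipped = report$n_allele_flipped,
         n_strand_ambiguous_dropped = report$n_strand_ambiguous_dropped,
         n_unmatched = report$n_unmatched,
         log = report$log),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Serialise a fitted Cox model to JSON
#'
#' Coefficients, covariance, covariate means and the Breslow baseline
#' cumulative-hazard breakpoints, sufficient to reconstruct predictions.
#'
#' @param model A `cox_risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cox_model_json <- function(model, path) {
  jsonlite::write_json(
    list(cohort = model$spec$cohort,
         covariates = model$spec$covariates,
         terms = model$covariate_names,
         beta = unname(model$beta),
         covariance = model$covariance,
         means = unname(model$means),
         baseline = model$baseline,
         n_events = model$n_events,
         n_at_risk = model$n_at_risk,
         loglik = model$loglik),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path` (writer) or a `sim_config` (reader).
#' @export
write_sim_config_yaml <- function(config, path) {
  out <- unclass(config)
  out$covariate_effects <- as.list(out$covariate_effects)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  eff <- unlist(raw$covariate_effects)
  do.call(sim_config, c(
    raw[intersect(names(raw), setdiff(names(formals(sim_config)),
                                      "covariate_effects"))],
    list(covariate_effects = eff)
  ))
}
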