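# Synthetic-cohort generator: genotypes, discovery summary statistics,
# clinical covariates and censored event times with the proportional-hazards
# structure the downstream evaluation assumes.

# Default study conditions per cohort design. Sizes match the three age
# cohorts of the motivating study (2333 adult / 2229 youth / 2894 birth);
# per-SD hazard ratios are the unadjusted PS associations reported there;
# baseline scales are calibrated so an exponential baseline reproduces the
# reported 10- and 30-year cumulative incidences; dropout rates reproduce
# the reported person-years per participant.
.design_defaults <- list(
  adult = list(
    n_individuals = 2333L, true_ps_hr_per_sd = 1.31,
    baseline_hazard_scale = 28, censoring_rate = 0.10, admin_horizon = 25,
    analysis_horizon = 10
  ),
  youth = list(
    n_individuals = 2229L, true_ps_hr_per_sd = 1.59,
    baseline_hazard_scale = 95, censoring_rate = 0.11, admin_horizon = 25,
    analysis_horizon = 10
  ),
  birth = list(
    n_individuals = 2894L, true_ps_hr_per_sd = 1.47,
    baseline_hazard_scale = 104, censoring_rate = 0.03, admin_horizon = 45,
    analysis_horizon = 30
  )
)

# Generative log hazard ratios for the clinical covariates, taken from the
# adjusted Cox models of the motivating study (per decade of age, per unit
# of the continuous covariates, indicator contrasts otherwise).
.design_effects <- list(
  adult = c(age_dec = log(1.04), sexF = log(1.35),
            mother_yes = log(1.52), mother_unknown = log(1.45),
            father_yes = log(1.45), father_unknown = log(1.20),
            bmi = log(1.02), fpg = log(1.99), hba1c = log(1.08),
            twohpg = log(1.32)),
  youth = c(age_dec = log(2.11), sexF = log(1.40),
            mother_yes = log(2.46), mother_unknown = log(1.84),
            father_yes = log(1.88), father_unknown = log(1.01),
            bmiz = log(1.50), fpg = log(2.32), hba1c = log(1.06),
            twohpg = log(1.35)),
  birth = c(sexF = log(1.18),
            mother_yes = log(7.28), mother_unknown = log(0.871),
            father_yes = log(3.93), father_unknown = log(1.01),
            bw_low = log(1.56), bw_high = log(1.57))
)

#' Simulation configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator: genotype panel
#' dimensions, the genetic architecture of the discovery trait, the true
#' per-SD hazard ratio of the polygenic score, the Weibull baseline hazard,
#' and the censoring process. Defaults depend on `cohort_design` and emulate
#' the three age cohorts (adult / youth / birth) of a longitudinal diabetes
#' study: cohort sizes, event rates over the 10- or 30-year analysis
#' horizon, and mean follow-up are matched at those defaults.
#'
#' @param cohort_design One of `"adult"`, `"youth"`, `"birth"`. Controls
#'   which clinical covariates are generated and the default hazard scales.
#' @param n_individuals Number of people to simulate.
#' @param n_variants Number of variants on the genotype panel.
#' @param maf_range Range (low, high) from which per-variant minor allele
#'   frequencies are drawn uniformly; must lie inside (0.01, 0.5).
#' @param frac_causal Proportion of variants with a non-zero true effect on
#'   the discovery trait.
#' @param causal_effect_sd Standard deviation of true causal log odds
#'   ratios (typical common-variant effect sizes).
#' @param true_ps_hr_per_sd True hazard ratio per standard deviation of the
#'   (standardised) true polygenic score.
#' @param baseline_hazard_shape,baseline_hazard_scale Weibull baseline
#'   hazard parameters; shape 1 is an exponential baseline.
#' @param censoring_rate Exponential dropout rate per year (0 disables
#'   random censoring).
#' @param admin_horizon Administrative end of follow-up in years (`Inf`
#'   disables it). This is the maximum follow-up, not the analysis horizon.
#' @param analysis_horizon Default risk-prediction horizon in years
#'   (10 for adult/youth designs, 30 for birth).
#' @param covariate_effects Named numeric vector of generative log hazard
#'   ratios overriding the design defaults (use `numeric(0)`-style named
#'   entries of 0 to switch individual effects off, or `zero_covariates()`
#'   via `covariate_effects = "none"` to null them all).
#' @param dosage_noise Non-negative scalar; 0 keeps hard genotypes, larger
#'   values perturb dosages continuously (beta-distributed around the hard
#'   genotype) to mimic imputation uncertainty.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(cohort_design = c("adult", "youth", "birth"),
                       n_individuals = NULL,
                       n_variants = 300L,
                       maf_range = c(0.05, 0.5),
                       frac_causal = 0.5,
                       causal_effect_sd = 0.05,
                       true_ps_hr_per_sd = NULL,
                       baseline_hazard_shape = 1,
                       baseline_hazard_scale = NULL,
                       censoring_rate = NULL,
                       admin_horizon = NULL,
                       analysis_horizon = NULL,
                       covariate_effects = NULL,
                       dosage_noise = 0,
                       seed = 1L) {
  cohort_design <- match.arg(cohort_design)
  def <- .design_defaults[[cohort_design]]
  cfg <- list(
    cohort_design = cohort_design,
    n_individuals = n_individuals %||% def$n_individuals,
    n_variants = n_variants,
    maf_range = maf_range,
    frac_causal = frac_causal,
    causal_effect_sd = causal_effect_sd,
    true_ps_hr_per_sd = true_ps_hr_per_sd %||% def$true_ps_hr_per_sd,
    baseline_hazard_shape = baseline_hazard_shape,
    baseline_hazard_scale = baseline_hazard_scale %||% def$baseline_hazard_scale,
    censoring_rate = censoring_rate %||% def$censoring_rate,
    admin_horizon = admin_horizon %||% def$admin_horizon,
    analysis_horizon = analysis_horizon %||% def$analysis_horizon,
    dosage_noise = dosage_noise,
    seed = as.integer(seed)
  )
  eff <- .design_effects[[cohort_design]]
  if (identical(covariate_effects, "none")) {
    eff[] <- 0
  } else if (!is.null(covariate_effects)) {
    stopifnot(is.numeric(covariate_effects), !is.null(names(covariate_effects)))
    unknown <- setdiff(names(covariate_effects), names(eff))
    if (length(unknown) > 0) {
      stop_pgs(paste0("Unknown covariate effect(s) for the ", cohort_design,
                      " design: ", paste(unknown, collapse = ", ")),
               "pgsrisk_invalid_config")
    }
    eff[names(covariate_effects)] <- covariate_effects
  }
  cfg$covariate_effects <- eff
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$n_individuals, "n_individuals")
  assert_count(cfg$n_variants, "n_variants")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] >= cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0.01 - 1e-12 || cfg$maf_range[2] > 0.5) {
    stop_pgs("`maf_range` must be an ordered pair inside (0.01, 0.5].",
             "pgsrisk_invalid_config")
  }
  if (cfg$frac_causal < 0 || cfg$frac_causal > 1) {
    stop_pgs("`frac_causal` must lie in [0, 1].", "pgsrisk_invalid_config")
  }
  pos <- c(true_ps_hr_per_sd = cfg$true_ps_hr_per_sd,
           baseline_hazard_shape = cfg$baseline_hazard_shape,
           baseline_hazard_scale = cfg$baseline_hazard_scale,
           causal_effect_sd = cfg$causal_effect_sd)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0) {
    stop_pgs(paste0("Strictly positive value required for: ",
                    paste(bad, collapse = ", ")), "pgsrisk_invalid_config")
  }
  if (cfg$censoring_rate < 0 || cfg$dosage_noise < 0) {
    stop_pgs("`censoring_rate` and `dosage_noise` must be non-negative.",
             "pgsrisk_invalid_config")
  }
  if (cfg$admin_horizon <= 0 || cfg$analysis_horizon <= 0) {
    stop_pgs("Horizons must be positive.", "pgsrisk_invalid_config")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$cohort_design, " design: ",
      x$n_individuals, " individuals, ", x$n_variants, " variants, ",
      "true PS HR/SD ", format(x$true_ps_hr_per_sd), ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# Evaluate code under a seed, restoring the caller's RNG state afterwards.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a genotype dosage panel
#'
#' Draws per-variant effect-allele frequencies uniformly over `maf_range`
#' (randomly assigning the effect allele to the minor or major allele),
#' then draws each individual's dosage as a Hardy-Weinberg binomial count
#' of effect alleles. With `dosage_noise > 0`, hard genotypes are replaced
#' by beta-perturbed continuous dosages in `[0, 2]`, mimicking imputation.
#' Imputation info scores are drawn from a Beta(14, 1) distribution
#' (median approximately 0.95, matching high-quality imputation panels).
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix`: list with `dosages` (individuals x variants
#'   matrix), `sample_ids`, and `variants` (tibble with `chrom`, `pos`,
#'   `ea`, `oa`, `eaf`, `info`).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  nv <- config$n_variants
  with_rng_seed(derive_seed(config$seed, 1L), {
    chrom <- sort(sample(1:22, nv, replace = TRUE))
    pos <- integer(nv)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(2.4e8, length(idx)))
    }
    alleles <- t(vapply(seq_len(nv), function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    maf <- runif(nv, config$maf_range[1], config$maf_range[2])
    eaf <- ifelse(runif(nv) < 0.5, maf, 1 - maf)
    dos <- matrix(rbinom(n * nv, 2L, rep(eaf, each = n)), nrow = n, ncol = nv)
    if (config$dosage_noise > 0) {
      prec <- 1 / config$dosage_noise
      a <- dos * prec + 1
      b <- (2 - dos) * prec + 1
      dos <- matrix(2 * rbeta(n * nv, a, b), nrow = n, ncol = nv)
    }
    info <- rbeta(nv, 14, 1)
    geno_matrix(
      dosages = dos,
      sample_ids = sprintf("person_%05d", seq_len(n)),
      variants = tibble(
        chrom = chrom, pos = pos,
        ea = alleles[, 1], oa = alleles[, 2],
        eaf = eaf, info = info
      )
    )
  })
}

#' Construct a genotype matrix object
#'
#' @param dosages Numeric matrix, individuals in rows, variants in columns,
#'   values in `[0, 2]` (`NA` allowed for missing dosages).
#' @param sample_ids Character vector of row identifiers.
#' @param variants Tibble with columns `chrom`, `pos`, `ea`, `oa`, `eaf`
#'   and optionally `info` (defaults to 1).
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (!"info" %in% names(variants)) variants$info <- 1
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop_pgs("Dosages must lie in [0, 2].", "pgsrisk_validation")
  }
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    stop_pgs("Duplicate variant keys in genotype matrix.", "pgsrisk_validation")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- key
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variants = variants),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$sample_ids), " individuals x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ea, variants$oa, sep = ":")
}

# Position key ignoring allele order, used for matching summary statistics.
position_key <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Simulate discovery GWAS summary statistics
#'
#' Assigns each panel variant a true log odds ratio (point mass at zero for
#' non-causal variants, normal with SD `causal_effect_sd` for the causal
#' fraction), then reports a noisy estimate whose standard error follows
#' the standard GWAS approximation `1 / sqrt(2 N p (1 - p))` for a
#' discovery sample of size `discovery_n` at effect-allele frequency `p`.
#' P-values are two-sided Wald.
#'
#' @param geno A `geno_matrix` (provides the variant panel and frequencies).
#' @param config A [sim_config()].
#' @param discovery_n Effective discovery sample size (larger values give
#'   more precise reported effects).
#' @return A summary-statistics tibble with columns `chrom`, `pos`, `ea`,
#'   `oa`, `beta`, `se`, `p`, `eaf`, plus `beta_true` (the latent truth
#'   used by [simulate_cohort()]; dropped on export).
#' @export
simulate_summary_stats <- function(geno, config, discovery_n = 1e5) {
  validate_sim_config(config)
  if (!is.numeric(discovery_n) || discovery_n <= 0) {
    stop_pgs("`discovery_n` must be positive.", "pgsrisk_invalid_config")
  }
  v <- geno$variants
  nv <- nrow(v)
  with_rng_seed(derive_seed(config$seed, 2L), {
    n_causal <- round(config$frac_causal * nv)
    beta_true <- numeric(nv)
    if (n_causal > 0) {
      causal <- sample.int(nv, n_causal)
      beta_true[causal] <- rnorm(n_causal, 0, config$causal_effect_sd)
    }
    se <- 1 / sqrt(2 * discovery_n * v$eaf * (1 - v$eaf))
    beta <- beta_true + rnorm(nv, 0, se)
    p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
    tibble(chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa,
           beta = beta, se = se, p = p, eaf = v$eaf, beta_true = beta_true)
  })
}

# Clinical covariates for one cohort design. Marginal distributions are
# package choices (the motivating study publishes only baseline summaries);
# only the hazard-model structure matters for method validation.
simulate_covariates <- function(design, n) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  par_cat <- function(n, p_yes, p_no) {
    sample(c("yes", "no", "unknown"), n, replace = TRUE,
           prob = c(p_yes, p_no, 1 - p_yes - p_no))
  }
  sex <- sample(c("F", "M"), n, replace = TRUE)
  if (design == "adult") {
    fpg <- clamp(rnorm(n, 5.4, 0.5), 3.5, 6.9)
    tibble(
      sex = sex,
      baseline_age = clamp(rnorm(n, 35, 11), 20, 75),
      bmi = clamp(rnorm(n, 31, 6.5), 17, 60),
      fpg = fpg,
      hba1c = clamp(31 + 4 * (fpg - 5.4) + rnorm(n, 0, 3), 20, 46),
      twohpg = clamp(6.0 + 1.5 * (fpg - 5.4) + rnorm(n, 0, 1.6), 2, 11),
      mother_diab = par_cat(n, 0.25, 0.55),
      father_diab = par_cat(n, 0.25, 0.55),
      birthweight_g = NA_real_
    )
  } else if (design == "youth") {
    fpg <- clamp(rnorm(n, 5.0, 0.4), 3.5, 6.9)
    tibble(
      sex = sex,
      baseline_age = clamp(rnorm(n, 12, 4), 5, 19.9),
      bmi = rnorm(n, 0.8, 1.0),  # modified BMI z score for the youth design
      fpg = fpg,
      hba1c = clamp(30 + 4 * (fpg - 5.0) + rnorm(n, 0, 2.5), 20, 46),
      twohpg = clamp(5.6 + 1.3 * (fpg - 5.0) + rnorm(n, 0, 1.4), 2, 11),
      mother_diab = par_cat(n, 0.30, 0.50),
      father_diab = par_cat(n, 0.30, 0.50),
      birthweight_g = NA_real_
    )
  } else {
    tibble(
      sex = sex,
      baseline_age = 0,
      bmi = NA_real_, fpg = NA_real_, hba1c = NA_real_, twohpg = NA_real_,
      mother_diab = par_cat(n, 0.10, 0.70),
      father_diab = par_cat(n, 0.10, 0.70),
      birthweight_g = clamp(rnorm(n, 3400, 550), 1500, 5500)
    )
  }
}

# Expand covariates into the generative linear-predictor terms
# (indicator encodings match the analysis models; see default_model_spec).
covariate_terms <- function(cov, design) {
  out <- tibble(
    sexF = as.numeric(cov$sex == "F"),
    mother_yes = as.numeric(cov$mother_diab == "yes"),
    mother_unknown = as.numeric(cov$mother_diab == "unknown"),
    father_yes = as.numeric(cov$father_diab == "yes"),
    father_unknown = as.numeric(cov$father_diab == "unknown")
  )
  if (design == "adult") {
    out$age_dec <- cov$baseline_age / 10
    out$bmi <- cov$bmi
    out$fpg <- cov$fpg
    out$hba1c <- cov$hba1c
    out$twohpg <- cov$twohpg
  } else if (design == "youth") {
    out$age_dec <- cov$baseline_age / 10
    out$bmiz <- cov$bmi
    out$fpg <- cov$fpg
    out$hba1c <- cov$hba1c
    out$twohpg <- cov$twohpg
  } else {
    out$bw_low <- as.numeric(cov$birthweight_g < 3000)
    out$bw_high <- as.numeric(cov$birthweight_g > 4000)
  }
  out
}

# True-score standardisation used by the generator: weighted allele sum of
# the true effects, z-scored over a reference set of people.
true_standardized_ps <- function(geno, true_effects) {
  beta <- true_effects$beta_true %||% true_effects$beta
  raw <- as.vector(geno$dosages %*% beta)
  s <- sd(raw)
  if (!is.finite(s) || s == 0) return(rep(0, length(raw)))
  (raw - mean(raw)) / s
}

simulate_cohort_impl <- function(design, config, ps_std, cov, u_event, u_censor,
                                 ids) {
  eff <- config$covariate_effects
  terms <- covariate_terms(cov, design)
  missing_terms <- setdiff(names(eff), names(terms))
  if (length(missing_terms) > 0) {
    stop_pgs(paste0("Covariate specs missing for design '", design, "': ",
                    paste(missing_terms, collapse = ", ")),
             "pgsrisk_invalid_config")
  }
  X <- as.matrix(terms[, names(eff), drop = FALSE])
  X <- sweep(X, 2, colMeans(X))  # centred so the baseline scale is marginal
  lp <- log(config$true_ps_hr_per_sd) * ps_std + as.vector(X %*% eff)
  # Weibull proportional hazards: S(t | lp) = exp(-(t/scale)^shape * e^lp)
  t_event <- config$baseline_hazard_scale *
    (-log(u_event) / exp(lp))^(1 / config$baseline_hazard_shape)
  t_cens <- if (config$censoring_rate > 0) {
    -log(u_censor) / config$censoring_rate
  } else {
    rep(Inf, length(u_censor))
  }
  t_cens <- pmin(t_cens, config$admin_horizon)
  followup <- pmin(t_event, t_cens)
  followup <- pmax(followup, 1e-8)  # followup_time strictly positive
  tibble(
    id = ids,
    cohort = design,
    baseline_age = cov$baseline_age,
    followup_time = followup,
    event = as.integer(t_event <= t_cens),
    ps_true = ps_std,
    true_lp = lp
  ) %>%
    dplyr::bind_cols(cov[setdiff(names(cov), c("baseline_age"))])
}

#' Simulate a single cohort with censored event times
#'
#' Generates clinical covariates for the configured design, combines them
#' with the standardised true polygenic score into a proportional-hazards
#' linear predictor (clinical log hazard ratios from the design defaults,
#' covariates centred at their sample means), and draws Weibull event times
#' plus exponential/administrative censoring.
#'
#' @param geno A `geno_matrix` covering the cohort.
#' @param true_effects Summary-statistics tibble carrying the true effects
#'   (`beta_true` column; reported `beta` is used as a fallback).
#' @param config A [sim_config()].
#' @return A cohort tibble: `id`, `cohort`, `baseline_age`,
#'   `followup_time`, `event`, clinical covariates, plus the latent
#'   `ps_true` (standardised true score) and `true_lp` (linear
#'   predictor), kept for diagnostics and oracle checks.
#' @export
simulate_cohort <- function(geno, true_effects, config) {
  validate_sim_config(config)
  n <- length(geno$sample_ids)
  ps_std <- true_standardized_ps(geno, true_effects)
  with_rng_seed(derive_seed(config$seed, 3L), {
    cov <- simulate_covariates(config$cohort_design, n)
    u_event <- runif(n)
    u_censor <- runif(n)
    simulate_cohort_impl(config$cohort_design, config, ps_std, cov,
                         u_event, u_censor, geno$sample_ids)
  })
}

#' Simulate overlapping birth/youth/adult cohorts from one person registry
#'
#' Builds a shared registry of persons, assigns each cohort a subset so
#' that a controllable fraction of persons appears in more than one cohort,
#' and simulates each cohort's covariates and follow-up from its own
#' configuration. Event and censoring uniforms are drawn once per person
#' and shared across cohorts, so the same person's outcomes in different
#' cohorts are strongly positively dependent (as they are when one person
#' is followed from several baselines), while each cohort marginally obeys
#' its configured proportional-hazards law. The true polygenic score is
#' standardised across the whole registry (the "entire study population").
#'
#' @param configs List of [sim_config()] objects, one per cohort, with
#'   distinct `cohort_design`s.
#' @param overlap Fraction in `[0, 1]` controlling how much cohorts share:
#'   0 gives disjoint cohorts, 1 makes every cohort a subset of the largest.
#'   The default 0.59 yields roughly 4770 distinct persons for the default
#'   cohort sizes.
#' @param seed Integer seed for the registry, genotypes and all cohorts.
#' @return List with `cohorts` (named list of cohort tibbles),
#'   `membership` (tibble `id`, `cohort`, one row per cohort appearance),
#'   `genotypes` (registry-wide `geno_matrix`), and `sumstats`.
#' @export
simulate_overlapping_cohorts <- function(configs, overlap = 0.59, seed = 1L) {
  if (overlap < 0 || overlap > 1) {
    stop_pgs("`overlap` must lie in [0, 1].", "pgsrisk_invalid_config")
  }
  designs <- vapply(configs, function(cfg) cfg$cohort_design, character(1))
  if (anyDuplicated(designs)) {
    stop_pgs("Each config must have a distinct cohort_design.",
             "pgsrisk_invalid_config")
  }
  names(configs) <- designs
  n_j <- vapply(configs, function(cfg) as.integer(cfg$n_individuals), integer(1))
  n_total <- sum(n_j)
  n_registry <- as.integer(round(n_total - overlap * (n_total - max(n_j))))

  reg_cfg <- configs[[which.max(n_j)]]
  reg_cfg$n_individuals <- n_registry
  reg_cfg$seed <- derive_seed(seed, 11L)
  geno <- simulate_genotypes(reg_cfg)
  stats <- simulate_summary_stats(geno, reg_cfg)
  ps_std <- true_standardized_ps(geno, stats)

  with_rng_seed(derive_seed(seed, 12L), {
    u_event <- runif(n_registry)
    u_censor <- runif(n_registry)
    # Largest cohort is assigned last and absorbs any uncovered persons, so
    # (almost) every registry person appears in at least one cohort.
    ord <- order(n_j)
    members <- vector("list", length(configs))
    names(members) <- designs
    if (overlap == 0) {
      stops <- cumsum(n_j)
      starts <- c(1L, head(stops, -1) + 1L)
      for (k in seq_along(configs)) {
        members[[k]] <- seq.int(starts[k], stops[k])
      }
    } else {
      covered <- rep(FALSE, n_registry)
      for (k in head(ord, -1)) {
        members[[k]] <- sort(sample.int(n_registry, n_j[k]))
        covered[members[[k]]] <- TRUE
      }
      k_last <- ord[length(ord)]
      uncovered <- which(!covered)
      if (length(uncovered) >= n_j[k_last]) {
        members[[k_last]] <- sort(sample(uncovered, n_j[k_last]))
      } else {
        extra <- sample(which(covered), n_j[k_last] - length(uncovered))
        members[[k_last]] <- sort(c(uncovered, extra))
      }
    }
    cohorts <- vector("list", length(configs))
    names(cohorts) <- designs
    for (k in seq_along(configs)) {
      cfg <- configs[[k]]
      idx <- members[[k]]
      cov <- simulate_covariates(cfg$cohort_design, length(idx))
      cohorts[[k]] <- simulate_cohort_impl(
        cfg$cohort_design, cfg, ps_std[idx], cov,
        u_event[idx], u_censor[idx], geno$sample_ids[idx]
      )
    }
    membership <- purrr::map_dfr(cohorts, ~ dplyr::select(.x, id, cohort))
    list(cohorts = cohorts, membership = membership,
         genotypes = geno, sumstats = stats)
  })
}
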