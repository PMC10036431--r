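# Cox proportional-hazards modelling: per-cohort model specifications,
# fitting (Breslow ties), hazard-ratio tables, the Breslow baseline
# cumulative hazard, and predicted cumulative incidence at fixed horizons.

#' Model specification for a cohort
#'
#' Describes the covariate blocks of a Cox model and how they are encoded:
#' `age` enters per decade, `sex` as a female indicator (male reference),
#' `mother`/`father` as two indicators (diabetic, unknown; non-diabetic
#' parent is the reference), `birthweight` as two indicators
#' (below 3000 g, above 4000 g; 3000-4000 g reference), `ps` as the
#' standardised polygenic score (hazard ratio per SD), and the remaining
#' continuous terms as-is.
#'
#' @param cohort Cohort design label (`"adult"`, `"youth"`, `"birth"`).
#' @param covariates Character vector of covariate blocks among
#'   `age, sex, mother, father, bmi, bmiz, fpg, hba1c, twohpg,
#'   birthweight, ps`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(cohort, covariates) {
  known <- c("age", "sex", "mother", "father", "bmi", "bmiz", "fpg",
             "hba1c", "twohpg", "birthweight", "ps")
  bad <- setdiff(covariates, known)
  if (length(bad) > 0) {
    stop_pgs(paste0("Unknown covariate block(s): ",
                    paste(bad, collapse = ", ")), "pgsrisk_invalid_config")
  }
  structure(list(cohort = cohort, covariates = covariates),
            class = "model_spec")
}

#' Default model specification per cohort design
#'
#' Adult and youth designs use age, sex, parental diabetes, adiposity
#' (BMI, or the modified BMI z score in youth), FPG and HbA1c; the birth
#' design uses sex, parental diabetes and dichotomised birthweight.
#'
#' @param cohort Cohort design label.
#' @param include_2hpg Add 2-hour plasma glucose (adult/youth only).
#' @param include_ps Add the standardised polygenic score.
#' @param include_hba1c Drop HbA1c when `FALSE` (mirrors analyses
#'   restricted to eras without HbA1c measurements).
#' @return A [model_spec()].
#' @export
default_model_spec <- function(cohort = c("adult", "youth", "birth"),
                               include_2hpg = FALSE, include_ps = FALSE,
                               include_hba1c = TRUE) {
  cohort <- match.arg(cohort)
  covs <- switch(cohort,
    adult = c("age", "sex", "mother", "father", "bmi", "fpg",
              if (include_hba1c) "hba1c", if (include_2hpg) "twohpg"),
    youth = c("age", "sex", "mother", "father", "bmiz", "fpg",
              if (include_hba1c) "hba1c", if (include_2hpg) "twohpg"),
    birth = c("sex", "mother", "father", "birthweight")
  )
  if (include_ps) covs <- c(covs, "ps")
  model_spec(cohort, covs)
}

# Expand a spec's covariate blocks into named numeric design columns.
# Returns a tibble; block membership is recorded in the "blocks" attribute
# so multi-level blocks can be dropped together.
build_design <- function(cohort, spec, ps = NULL) {
  need <- function(col, block) {
    if (!col %in% names(cohort) || anyNA(cohort[[col]])) {
      stop_pgs(paste0("Covariate '", col, "' required by block '", block,
                      "' is missing (or has missing values) in the cohort."),
               "pgsrisk_invalid_config")
    }
    cohort[[col]]
  }
  cols <- list()
  blocks <- character(0)
  add <- function(name, values, block) {
    cols[[name]] <<- as.numeric(values)
    blocks[name] <<- block
  }
  for (b in spec$covariates) {
    switch(b,
      age = add("age_dec", need("baseline_age", b) / 10, b),
      sex = add("sexF", need("sex", b) == "F", b),
      mother = {
        m <- need("mother_diab", b)
        add("mother_yes", m == "yes", b)
        add("mother_unknown", m == "unknown", b)
      },
      father = {
        f <- need("father_diab", b)
        add("father_yes", f == "yes", b)
        add("father_unknown", f == "unknown", b)
      },
      bmi = add("bmi", need("bmi", b), b),
      bmiz = add("bmiz", need("bmi", b), b),
      fpg = add("fpg", need("fpg", b), b),
      hba1c = add("hba1c", need("hba1c", b), b),
      twohpg = add("twohpg", need("twohpg", b), b),
      birthweight = {
        bw <- need("birthweight_g", b)
        add("bw_low", bw < 3000, b)
        add("bw_high", bw > 4000, b)
      },
      ps = {
        if (is.null(ps)) {
          stop_pgs("Spec includes 'ps' but no polygenic score was supplied.",
                   "pgsrisk_invalid_config")
        }
        s <- ps$standardized[match(cohort$id, ps$id)]
        if (anyNA(s)) {
          stop_pgs("Polygenic score does not cover every cohort member.",
                   "pgsrisk_validation")
        }
        add("ps", s, b)
      }
    )
  }
  X <- as.matrix(as_tibble(cols))
  structure(X, blocks = blocks)
}

#' Fit a Cox proportional-hazards model for a cohort
#'
#' Maximises the Cox partial likelihood (Breslow tie handling by default,
#' Efron available) for the covariates encoded by the model specification,
#' and computes the Breslow step-function estimate of the baseline
#' cumulative hazard with the linear predictor centred at the covariate
#' means. Fitting is delegated to [survival::coxph()].
#'
#' @param cohort Cohort tibble (`id`, `followup_time`, `event`, clinical
#'   covariates).
#' @param spec A [model_spec()].
#' @param ps Optional standardised polygenic score (required when the spec
#'   contains a `ps` block).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_risk_model`: the fitted coefficients and covariance,
#'   the Breslow baseline cumulative hazard, covariate means, and event
#'   counts. Supports [tidy()], [glance()], [hr_table()] and
#'   [predicted_cumulative_incidence()].
#' @export
fit_cox <- function(cohort, spec, ps = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(cohort$event) < 2) {
    stop_pgs("At least 2 events are required to fit a Cox model.",
             "pgsrisk_validation")
  }
  X <- build_design(cohort, spec, ps)
  # Cox covariates are identified only up to centring, so a constant
  # column (or any collinearity with the implicit intercept) is degenerate.
  if (qr(sweep(X, 2, colMeans(X)))$rank < ncol(X)) {
    stop_pgs("Design matrix is rank deficient after encoding.",
             "pgsrisk_validation")
  }
  df <- as.data.frame(X)
  df$.time <- cohort$followup_time
  df$.event <- cohort$event
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~", paste(colnames(X), collapse = " + ")
  ))
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = ties, x = FALSE, model = FALSE),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (any(grepl("infinite", warn_msgs)) || any(abs(coef(fit)) > 15)) {
    stop_pgs(paste0("Monotone partial likelihood (perfect separation) ",
                    "detected: |beta| diverges for ",
                    paste(names(coef(fit))[abs(coef(fit)) > 15],
                          collapse = ", ")),
             "pgsrisk_separation")
  }
  if (any(grepl("Ran out of iterations", warn_msgs))) {
    stop_pgs("Cox fit did not converge.", "pgsrisk_nonconvergence")
  }
  means <- colMeans(X)
  lp <- as.vector(X %*% coef(fit)) - sum(means * coef(fit))
  baseline <- breslow_baseline(cohort$followup_time, cohort$event, lp,
                               ties = ties)
  structure(list(
    fit = fit,
    spec = spec,
    ties = ties,
    covariate_names = colnames(X),
    blocks = attr(X, "blocks"),
    beta = coef(fit),
    covariance = fit$var,
    means = means,
    baseline = baseline,
    n_events = sum(cohort$event),
    n_at_risk = nrow(cohort),
    max_time = max(cohort$followup_time),
    loglik = fit$loglik[2],
    converged = TRUE
  ), class = "cox_risk_model")
}

# Breslow step-function estimate of the baseline cumulative hazard,
# H0(t) = sum over event times t_j <= t of d_j / sum_{i at risk} exp(lp_i).
# With Efron ties the tie correction is applied to the denominator.
breslow_baseline <- function(time, event, lp, ties = "breslow") {
  elp <- exp(lp)
  times <- sort(unique(time[event == 1]))
  haz <- numeric(length(times))
  for (j in seq_along(times)) {
    t_j <- times[j]
    at_risk <- sum(elp[time >= t_j])
    tied <- which(event == 1 & time == t_j)
    d <- length(tied)
    if (ties == "breslow" || d == 1) {
      haz[j] <- d / at_risk
    } else {
      tied_sum <- sum(elp[tied])
      haz[j] <- sum(1 / (at_risk - (seq_len(d) - 1) / d * tied_sum))
    }
  }
  tibble(time = times, hazard = haz, cumhaz = cumsum(haz))
}

#' @export
print.cox_risk_model <- function(x, ...) {
  cat("<cox_risk_model> cohort:", x$spec$cohort,
      "| events:", x$n_events, "/", x$n_at_risk, "at risk\n")
  print(hr_table(x))
  invisible(x)
}

#' Hazard-ratio table for a fitted Cox model
#'
#' @param model A `cox_risk_model`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `term`, `hr`, `lo`, `hi` (Wald interval,
#'   exp-symmetric about the HR on the log scale) and two-sided Wald `p`.
#' @export
hr_table <- function(model, conf_level = 0.95) {
  beta <- unname(model$beta)
  se <- unname(sqrt(diag(model$covariance)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = model$covariate_names,
    hr = exp(beta),
    lo = exp(beta - z * se),
    hi = exp(beta + z * se),
    p = 2 * pnorm(-abs(beta / se))
  )
}

#' @export
tidy.cox_risk_model <- function(x, exponentiate = FALSE,
                                conf_level = 0.95, ...) {
  se <- sqrt(diag(x$covariance))
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$beta
  lo <- est - z * se
  hi <- est + z * se
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  tibble(
    term = x$covariate_names,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = unname(2 * pnorm(-abs(x$beta / se))),
    conf.low = unname(lo),
    conf.high = unname(hi)
  )
}

#' @export
glance.cox_risk_model <- function(x, ...) {
  tibble(
    n = x$n_at_risk,
    n_events = x$n_events,
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$beta),
    concordance = unname(x$fit$concordance["concordance"])
  )
}

# Linear predictor (centred at the fit-time covariate means) for a cohort.
model_lp <- function(model, cohort, ps = NULL) {
  X <- build_design(cohort, model$spec, ps)
  as.vector(X %*% model$beta) - sum(model$means * model$beta)
}

#' Predicted cumulative incidence at a fixed horizon
#'
#' Evaluates `1 - exp(-H0(horizon) * exp(lp_i))` for every individual,
#' with `H0` the Breslow baseline cumulative hazard and `lp` centred as at
#' fit time. Horizons beyond the last observed follow-up time of the
#' fitting data are refused unless extrapolation is explicitly allowed.
#'
#' @param model A `cox_risk_model`.
#' @param cohort Cohort tibble to predict for.
#' @param horizon Prediction horizon in years.
#' @param ps Polygenic score, if the model spec includes a `ps` block.
#' @param allow_extrapolation Permit `horizon` beyond the last observed
#'   time (the baseline hazard is then frozen at its last value).
#' @param label Model label recorded on the prediction.
#' @return A risk-prediction tibble: `id`, `horizon`, `probability`,
#'   `model_label`, plus the linear predictor `lp`.
#' @export
predicted_cumulative_incidence <- function(model, cohort, horizon, ps = NULL,
                                           allow_extrapolation = FALSE,
                                           label = "model") {
  if (horizon <= 0 && horizon != 0) {
    stop_pgs("`horizon` must be non-negative.", "pgsrisk_invalid_config")
  }
  if (horizon > model$max_time && !allow_extrapolation) {
    stop_pgs(sprintf(paste0("Horizon %.3g exceeds the last observed time ",
                            "%.3g; set allow_extrapolation = TRUE to force."),
                     horizon, model$max_time),
             "pgsrisk_extrapolation")
  }
  lp <- model_lp(model, cohort, ps)
  idx <- findInterval(horizon, model$baseline$time)
  h0 <- if (idx == 0L) 0 else model$baseline$cumhaz[idx]
  tibble(
    id = cohort$id,
    horizon = horizon,
    probability = 1 - exp(-h0 * exp(lp)),
    model_label = label,
    lp = lp
  )
}

#' Observed and predicted cumulative incidence by risk group
#'
#' Groups individuals into quantile bins of a risk variable (polygenic
#' score deciles, or percentile bins of the clinical linear predictor) and
#' reports the Kaplan-Meier complement at the horizon within each group,
#' alongside the mean model-predicted probability when predictions are
#' supplied.
#'
#' @param cohort Cohort tibble.
#' @param values Per-person risk values aligned with `cohort` rows.
#' @param horizon Horizon in years.
#' @param n_groups Number of quantile groups (default 10: deciles).
#' @param predictions Optional risk-prediction tibble (joined on `id`).
#' @return Tibble with one row per group: `group`, `n`, `n_events`,
#'   `observed` (KM incidence at the horizon) and `predicted` (mean
#'   predicted probability, `NA` when no predictions given).
#' @export
group_cumulative_incidence <- function(cohort, values, horizon,
                                       n_groups = 10, predictions = NULL) {
  if (sum(cohort$event) < 1) {
    stop_pgs("At least one event is required.", "pgsrisk_validation")
  }
  if (length(unique(values)) < n_groups) {
    stop_pgs("Empty or degenerate risk group (too few distinct values).",
             "pgsrisk_degenerate_grouping")
  }
  grp <- dplyr::ntile(values, n_groups)
  pred <- rep(NA_real_, nrow(cohort))
  if (!is.null(predictions)) {
    pred <- predictions$probability[match(cohort$id, predictions$id)]
  }
  purrr::map_dfr(seq_len(n_groups), function(g) {
    rows <- grp == g
    tibble(
      group = g,
      n = sum(rows),
      n_events = sum(cohort$event[rows]),
      observed = km_event_prob(cohort$followup_time[rows],
                               cohort$event[rows], horizon),
      predicted = mean(pred[rows])
    )
  })
}

#' Predicted-risk surface over polygenic score and clinical risk
#'
#' Evaluates model-based cumulative incidence at the horizon on a grid of
#' polygenic-score values (in SD units) crossed with percentiles of the
#' clinical linear predictor (the model's linear predictor with the score
#' contribution removed), showing the separate contributions of genetic
#' and clinical risk.
#'
#' @param model A `cox_risk_model` whose spec includes a `ps` block.
#' @param cohort Cohort tibble used to locate the clinical-lp percentiles.
#' @param horizon Horizon in years.
#' @param ps Polygenic score used at fit time.
#' @param ps_values Grid of standardised score values (default -2..2).
#' @param percentiles Clinical-risk percentiles (default 10, 25, 50, 75, 90).
#' @return Tibble `ps_value`, `clinical_percentile`, `probability`.
#' @export
predicted_risk_surface <- function(model, cohort, horizon, ps,
                                   ps_values = seq(-2, 2, by = 0.5),
                                   percentiles = c(10, 25, 50, 75, 90)) {
  if (!"ps" %in% model$covariate_names) {
    stop_pgs("Model does not include a polygenic-score term.",
             "pgsrisk_invalid_config")
  }
  lp <- model_lp(model, cohort, ps)
  X <- build_design(cohort, model$spec, ps)
  ps_col <- X[, "ps"] - model$means["ps"]
  beta_ps <- model$beta["ps"]
  clin_lp <- lp - beta_ps * ps_col
  q <- quantile(clin_lp, probs = percentiles / 100, names = FALSE)
  idx <- findInterval(horizon, model$baseline$time)
  h0 <- if (idx == 0L) 0 else model$baseline$cumhaz[idx]
  tidyr::expand_grid(ps_value = ps_values,
                     clinical_percentile = percentiles) %>%
    mutate(
      probability = 1 - exp(-h0 * exp(
        q[match(.data$clinical_percentile, percentiles)] +
          beta_ps * (.data$ps_value - model$means["ps"])
      ))
    )
}

#' Calibration of predicted risk against observed incidence
#'
#' Bins individuals by deciles (or `n_bins` quantiles) of predicted
#' probability and compares the mean prediction in each bin with the
#' Kaplan-Meier incidence at the horizon, with a KM confidence interval.
#'
#' @param pred Risk-prediction tibble.
#' @param cohort Cohort tibble (joined on `id`).
#' @param n_bins Number of quantile bins (default 10).
#' @return Tibble `bin`, `n`, `mean_predicted`, `observed`, `lo`, `hi`.
#' @export
calibration_bins <- function(pred, cohort, n_bins = 10) {
  if (n_bins < 2) stop_pgs("`n_bins` must be >= 2.", "pgsrisk_invalid_config")
  dat <- dplyr::inner_join(
    dplyr::select(pred, "id", "horizon", "probability"),
    dplyr::select(cohort, "id", "followup_time", "event"),
    by = "id"
  )
  horizon <- dat$horizon[1]
  if (length(unique(dat$probability)) == 1L) {
    warn("All predictions identical; returning a single calibration bin.")
    bins <- rep(1L, nrow(dat))
    n_bins <- 1L
  } else {
    bins <- dplyr::ntile(dat$probability, n_bins)
  }
  purrr::map_dfr(seq_len(n_bins), function(b) {
    rows <- bins == b
    ci <- km_event_prob_ci(dat$followup_time[rows], dat$event[rows], horizon)
    tibble(bin = b, n = sum(rows),
           mean_predicted = mean(dat$probability[rows]),
           observed = ci["est"], lo = ci["lo"], hi = ci["hi"])
  })
}

# Fast unadjusted single-covariate Cox fit (Breslow ties) via the survival
# package's internal fitter; bootstrap multiplicities enter as case weights.
fast_cox1 <- function(time, status, x, weights = NULL) {
  if (!is.null(weights)) {
    keep <- weights > 0
    time <- time[keep]; status <- status[keep]; x <- x[keep]
    weights <- as.double(weights[keep])
  }
  fit <- survival::coxph.fit(
    x = matrix(x, ncol = 1), y = Surv(time, status), strata = NULL,
    offset = NULL, init = 0, control = coxph.control(), weights = weights,
    method = "breslow", rownames = NULL
  )
  c(beta = unname(fit$coefficients[1]),
    se = sqrt(fit$var[1, 1]))
}
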