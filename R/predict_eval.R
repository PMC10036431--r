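# Model evaluation for censored outcomes: fixed-horizon status
# classification, Harrell's C / AUC differences, continuous net
# reclassification improvement, and decision-curve net benefit.

#' Classify each person's status at a fixed horizon
#'
#' A person is an `event` if their event occurred at or before the
#' horizon, a `nonevent` if they were followed beyond the horizon without
#' the event (regardless of later status), and `excluded` if censored
#' before the horizon (their status at the horizon is unknown).
#'
#' @param cohort Cohort tibble (`id`, `followup_time`, `event`).
#' @param horizon Horizon in years (> 0).
#' @return Tibble `id`, `status` (factor event/nonevent/excluded).
#' @export
status_at_horizon <- function(cohort, horizon) {
  if (horizon <= 0) stop_pgs("`horizon` must be > 0.", "pgsrisk_invalid_config")
  status <- dplyr::case_when(
    cohort$event == 1 & cohort$followup_time <= horizon ~ "event",
    cohort$followup_time >= horizon ~ "nonevent",
    TRUE ~ "excluded"
  )
  tibble(id = cohort$id,
         status = factor(status, levels = c("event", "nonevent", "excluded")))
}

#' Harrell's concordance index for censored data
#'
#' Probability, over usable pairs (pairs whose outcome ordering is
#' determinable under censoring), that the individual with the earlier
#' event received the higher risk score; ties in the score count one half.
#' Equivalent to the AUC of the ROC curve for risk prediction at a fixed
#' follow-up. The pair counting is delegated to
#' [survival::concordance()]; an exhaustive pair enumeration oracle backs
#' it in the test suite.
#'
#' @param time,event Follow-up times and event indicators.
#' @param score Risk score (higher = higher predicted risk).
#' @param ci `"none"`, `"asymptotic"` (infinitesimal-jackknife SE from the
#'   concordance computation) or `"bootstrap"` (resampling individuals).
#' @param n_boot,seed Bootstrap settings when `ci = "bootstrap"`.
#' @return A `concordance_result`: list with `c_statistic`, pair counts
#'   (`n_concordant`, `n_discordant`, `n_tied`, `n_usable_pairs`) and
#'   `ci95`.
#' @export
concordance_index <- function(time, event, score,
                              ci = c("none", "asymptotic", "bootstrap"),
                              n_boot = 200, seed = 1L) {
  ci <- match.arg(ci)
  if (sum(event) < 1) {
    stop_pgs("At least one event is required.", "pgsrisk_validation")
  }
  fit <- concordance(Surv(time, event) ~ score, reverse = TRUE,
                     timewt = "n")
  cnt <- fit$count
  n_conc <- unname(cnt["concordant"])
  n_disc <- unname(cnt["discordant"])
  n_tied <- unname(cnt["tied.x"])
  usable <- n_conc + n_disc + n_tied
  if (usable == 0) {
    stop_pgs("No usable pairs under censoring.", "pgsrisk_degenerate")
  }
  cstat <- (n_conc + 0.5 * n_tied) / usable
  ci95 <- c(NA_real_, NA_real_)
  if (ci == "asymptotic") {
    se <- sqrt(fit$var)
    ci95 <- cstat + c(-1, 1) * qnorm(0.975) * se
  } else if (ci == "bootstrap") {
    n <- length(time)
    boots <- with_rng_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) == 0) return(NA_real_)
        f <- concordance(Surv(time[idx], event[idx]) ~ score[idx],
                         reverse = TRUE, timewt = "n")
        k <- f$count
        u <- k["concordant"] + k["discordant"] + k["tied.x"]
        unname((k["concordant"] + 0.5 * k["tied.x"]) / u)
      }, numeric(1))
    })
    ci95 <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(
    c_statistic = cstat,
    n_concordant = n_conc,
    n_discordant = n_disc,
    n_tied = n_tied,
    n_usable_pairs = usable,
    ci95 = ci95
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> C = %.4f (%d usable pairs)\n",
              x$c_statistic, round(x$n_usable_pairs)))
  invisible(x)
}

#' Difference between two AUC / C-statistic values
#'
#' The increment in discrimination from augmenting a model:
#' `auc_full - auc_base`.
#'
#' @param auc_base,auc_full C statistics of the base and augmented models.
#' @return The difference (delta AUC).
#' @export
auc_difference <- function(auc_base, auc_full) {
  auc_full - auc_base
}

#' Compare the AUC of two Cox models by paired bootstrap
#'
#' Computes Harrell's C for a base and an augmented model on the same
#' cohort (scores are the fitted linear predictors), their difference,
#' and a paired-bootstrap confidence interval and p-value: individuals
#' are resampled once per replicate and both models' scores are
#' re-evaluated on the same resample (optionally refitting the models).
#'
#' @param model_a,model_b Fitted `cox_risk_model`s on the same cohort
#'   (`model_b` typically nests `model_a`).
#' @param cohort Cohort tibble both models were fitted on.
#' @param ps Polygenic score (needed when either spec has a `ps` block).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param refit Refit both models on every replicate (slower; default
#'   `FALSE` re-evaluates the original linear predictors).
#' @return List with `auc_a`, `auc_b`, `delta_auc`, `ci95`, `p`,
#'   `n_boot`.
#' @export
compare_auc <- function(model_a, model_b, cohort, ps = NULL, n_boot = 1000,
                        seed = 1L, refit = FALSE) {
  lp_a <- model_lp(model_a, cohort, ps)
  lp_b <- model_lp(model_b, cohort, ps)
  time <- cohort$followup_time
  event <- cohort$event
  cstat <- function(t, e, s) {
    f <- concordance(Surv(t, e) ~ s, reverse = TRUE, timewt = "n")
    k <- f$count
    unname((k["concordant"] + 0.5 * k["tied.x"]) /
             (k["concordant"] + k["discordant"] + k["tied.x"]))
  }
  auc_a <- cstat(time, event, lp_a)
  auc_b <- cstat(time, event, lp_b)
  delta <- auc_difference(auc_a, auc_b)
  n <- nrow(cohort)
  deltas <- with_rng_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) < 2) return(NA_real_)
      if (refit) {
        boot <- cohort[idx, ]
        fa <- fit_cox(boot, model_a$spec, ps)
        fb <- fit_cox(boot, model_b$spec, ps)
        sa <- model_lp(fa, boot, ps)
        sb <- model_lp(fb, boot, ps)
      } else {
        sa <- lp_a[idx]
        sb <- lp_b[idx]
      }
      cstat(time[idx], event[idx], sb) - cstat(time[idx], event[idx], sa)
    }, numeric(1))
  })
  deltas <- deltas[!is.na(deltas)]
  se <- sd(deltas)
  p <- if (!is.finite(se) || se == 0) {
    if (abs(delta) < 1e-15) 1 else 0
  } else {
    2 * pnorm(-abs(delta / se))
  }
  list(
    auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
    ci95 = unname(quantile(deltas, c(0.025, 0.975))),
    p = p, se = se, n_boot = length(deltas)
  )
}

#' Continuous net reclassification improvement
#'
#' Compares the predicted probabilities of a base and an augmented model:
#' the event component is the net proportion of events assigned a higher
#' probability by the augmented model, the nonevent component the net
#' proportion of nonevents assigned a lower probability, and the NRI
#' their sum. Exact ties count as no reclassification; persons whose
#' status at the horizon is unknown (`excluded`) are omitted.
#'
#' @param pred_base,pred_full Risk-prediction tibbles on the same ids.
#' @param status Status tibble from [status_at_horizon()].
#' @return An `nri_result`: `event_component`, `nonevent_component`,
#'   `total`, counts, and (unfilled) `ci95`.
#' @export
continuous_nri <- function(pred_base, pred_full, status) {
  dat <- dplyr::inner_join(
    dplyr::select(pred_base, "id", base = "probability"),
    dplyr::select(pred_full, "id", full = "probability"),
    by = "id"
  ) %>%
    dplyr::inner_join(status, by = "id")
  if (nrow(dat) != nrow(pred_base)) {
    stop_pgs("Predictions and status must align on the same ids.",
             "pgsrisk_validation")
  }
  used <- dat$status != "excluded"
  ev <- used & dat$status == "event"
  ne <- used & dat$status == "nonevent"
  if (sum(ev) == 0 || sum(ne) == 0) {
    stop_pgs("Need at least one event and one nonevent after exclusions.",
             "pgsrisk_validation")
  }
  up <- dat$full > dat$base
  down <- dat$full < dat$base
  if (!any(up[used]) && !any(down[used])) {
    warn("All predictions tied between models; NRI carries no information.")
  }
  event_component <- mean(up[ev]) - mean(down[ev])
  nonevent_component <- mean(down[ne]) - mean(up[ne])
  structure(list(
    event_component = event_component,
    nonevent_component = nonevent_component,
    total = event_component + nonevent_component,
    ci95 = c(NA_real_, NA_real_),
    n_events = sum(ev),
    n_nonevents = sum(ne),
    n_excluded = sum(!used),
    horizon = pred_base$horizon[1]
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "<nri_result> NRI = %.4f (events %.4f + nonevents %.4f); %d ev / %d non-ev / %d excluded\n",
    x$total, x$event_component, x$nonevent_component,
    x$n_events, x$n_nonevents, x$n_excluded))
  if (!anyNA(x$ci95)) {
    cat(sprintf("  95%% CI (%.4f, %.4f)\n", x$ci95[1], x$ci95[2]))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the continuous NRI
#'
#' Percentile interval over individual-level resamples; the
#' event/nonevent classification is re-derived within every replicate.
#' Replicates without both an event and a nonevent are dropped and
#' counted.
#'
#' @param pred_base,pred_full Risk-prediction tibbles.
#' @param cohort Cohort tibble (provides follow-up for reclassification).
#' @param horizon Horizon in years.
#' @param n_boot Number of replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param conf_level Interval coverage (default 0.95).
#' @return An `nri_result` with `ci95` filled, plus attributes
#'   `boot_values` and `n_dropped`.
#' @export
nri_bootstrap_ci <- function(pred_base, pred_full, cohort, horizon,
                             n_boot = 1000, seed = 1L, conf_level = 0.95) {
  if (n_boot < 100) stop_pgs("`n_boot` must be >= 100.",
                             "pgsrisk_invalid_config")
  obs <- continuous_nri(pred_base, pred_full, status_at_horizon(cohort, horizon))
  base <- pred_base$probability[match(cohort$id, pred_base$id)]
  full <- pred_full$probability[match(cohort$id, pred_full$id)]
  n <- nrow(cohort)
  vals <- with_rng_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      t_i <- cohort$followup_time[idx]
      e_i <- cohort$event[idx]
      ev <- e_i == 1 & t_i <= horizon
      ne <- t_i >= horizon
      ne <- ne & !ev
      if (sum(ev) == 0 || sum(ne) == 0) return(NA_real_)
      up <- full[idx] > base[idx]
      down <- full[idx] < base[idx]
      (mean(up[ev]) - mean(down[ev])) + (mean(down[ne]) - mean(up[ne]))
    }, numeric(1))
  })
  n_dropped <- sum(is.na(vals))
  if (n_dropped > 0.1 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates dropped (no events or no nonevents).",
                 n_dropped, n_boot))
  }
  vals <- vals[!is.na(vals)]
  alpha <- 1 - conf_level
  obs$ci95 <- unname(quantile(vals, c(alpha / 2, 1 - alpha / 2)))
  attr(obs, "boot_values") <- vals
  attr(obs, "n_dropped") <- n_dropped
  obs
}

#' Per-predictor NRI for a model specification
#'
#' For every covariate block in the specification, compares the full model
#' with the model omitting that block (multi-level blocks are dropped as a
#' unit) and reports the continuous NRI at the cohort horizon.
#'
#' @param cohort Cohort tibble.
#' @param spec Full [model_spec()].
#' @param horizon Horizon in years.
#' @param ps Polygenic score, if the spec includes `ps`.
#' @return Tibble `term`, `event_component`, `nonevent_component`, `nri`;
#'   one row per predictor block (blocks whose reduced model fails to
#'   converge are flagged via a message and omitted).
#' @export
per_predictor_nri <- function(cohort, spec, horizon, ps = NULL) {
  full_fit <- fit_cox(cohort, spec, ps)
  pred_full <- predicted_cumulative_incidence(full_fit, cohort, horizon, ps,
                                              label = "full")
  status <- status_at_horizon(cohort, horizon)
  purrr::map_dfr(spec$covariates, function(block) {
    reduced_spec <- model_spec(spec$cohort, setdiff(spec$covariates, block))
    red_fit <- tryCatch(fit_cox(cohort, reduced_spec, ps),
                        error = function(e) NULL)
    if (is.null(red_fit)) {
      inform(paste0("Reduced model without '", block,
                    "' failed to converge; row omitted."))
      return(tibble())
    }
    pred_red <- predicted_cumulative_incidence(red_fit, cohort, horizon, ps,
                                               label = "reduced")
    nri <- continuous_nri(pred_red, pred_full, status)
    tibble(term = block,
           event_component = nri$event_component,
           nonevent_component = nri$nonevent_component,
           nri = nri$total)
  })
}

#' Net benefit of a prediction model at a threshold probability
#'
#' With `x` the proportion of the cohort whose predicted probability
#' reaches the threshold and `F` the Kaplan-Meier event probability by the
#' horizon among those selected, the net benefit is
#' `x * F - x * (1 - F) * pt / (1 - pt)` (the survival extension of
#' decision-curve analysis: true positives minus threshold-weighted false
#' positives among the selected). Selecting nobody gives 0 by convention.
#'
#' @param pred Risk-prediction tibble.
#' @param cohort Cohort tibble (joined on `id`).
#' @param horizon Horizon in years.
#' @param pt Threshold probability in (0, 1).
#' @return Scalar net benefit.
#' @export
net_benefit <- function(pred, cohort, horizon, pt) {
  if (pt <= 0 || pt >= 1) stop_pgs("`pt` must lie in (0, 1).",
                                   "pgsrisk_invalid_config")
  prob <- pred$probability[match(cohort$id, pred$id)]
  sel <- prob >= pt
  x <- mean(sel)
  if (x == 0) {
    inform(sprintf("No individual selected at pt = %.3g; net benefit 0.", pt))
    return(0)
  }
  f <- km_event_prob(cohort$followup_time[sel], cohort$event[sel], horizon)
  x * f - x * (1 - f) * pt / (1 - pt)
}

#' Decision curves for a set of prediction models
#'
#' Net benefit of each model across a grid of threshold probabilities,
#' with treat-all and treat-none reference strategies and the proportion
#' of the population selected at each threshold.
#'
#' @param predictions Named list of risk-prediction tibbles (one per
#'   model) on the same cohort.
#' @param cohort Cohort tibble.
#' @param horizon Horizon in years.
#' @param pt_grid Strictly increasing thresholds in (0, 1); the default
#'   0.01-0.60 in steps of 0.01 covers the clinically plausible range.
#' @return A `decision_curve` object: tibble `pt`, `model`,
#'   `net_benefit`, `proportion_selected` (including `treat_all` and
#'   `treat_none` rows), with the horizon as an attribute.
#' @export
decision_curve <- function(predictions, cohort, horizon,
                           pt_grid = seq(0.01, 0.60, by = 0.01)) {
  if (any(diff(pt_grid) <= 0) || any(pt_grid <= 0) || any(pt_grid >= 1)) {
    stop_pgs("`pt_grid` must be strictly increasing inside (0, 1).",
             "pgsrisk_invalid_config")
  }
  if (is.null(names(predictions))) {
    names(predictions) <- paste0("model_", seq_along(predictions))
  }
  km_all <- km_event_prob(cohort$followup_time, cohort$event, horizon)
  rows <- purrr::map_dfr(names(predictions), function(nm) {
    pred <- predictions[[nm]]
    prob <- pred$probability[match(cohort$id, pred$id)]
    purrr::map_dfr(pt_grid, function(pt) {
      tibble(pt = pt, model = nm,
             net_benefit = suppressMessages(
               net_benefit(pred, cohort, horizon, pt)),
             proportion_selected = mean(prob >= pt))
    })
  })
  ref <- dplyr::bind_rows(
    tibble(pt = pt_grid, model = "treat_all",
           net_benefit = km_all - (1 - km_all) * pt_grid / (1 - pt_grid),
           proportion_selected = 1),
    tibble(pt = pt_grid, model = "treat_none",
           net_benefit = 0, proportion_selected = 0)
  )
  structure(dplyr::bind_rows(rows, ref),
            horizon = horizon, class = c("decision_curve", class(rows)))
}

#' Relative improvement in net benefit between two models
#'
#' Percentage (and absolute) improvement of model B over model A at each
#' threshold where A's net benefit is positive.
#'
#' @param curve A [decision_curve()].
#' @param model_a,model_b Model labels present in the curve.
#' @return Tibble `pt`, `nb_a`, `nb_b`, `absolute`, `percent`.
#' @export
nb_improvement <- function(curve, model_a, model_b) {
  wide <- curve %>%
    filter(.data$model %in% c(model_a, model_b)) %>%
    dplyr::select("pt", "model", "net_benefit") %>%
    tidyr::pivot_wider(names_from = "model", values_from = "net_benefit")
  tibble(
    pt = wide$pt,
    nb_a = wide[[model_a]],
    nb_b = wide[[model_b]],
    absolute = wide[[model_b]] - wide[[model_a]],
    percent = ifelse(wide[[model_a]] > 0,
                     100 * (wide[[model_b]] - wide[[model_a]]) / wide[[model_a]],
                     NA_real_)
  )
}
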