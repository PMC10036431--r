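# Cox fitting against brute-force partial-likelihood oracles, Breslow
# baseline and predicted cumulative incidence, grouping and calibration.

test_that("single-covariate fits match brute-force likelihood maximisation", {
  set.seed(31)
  for (r in 1:5) {
    n <- 6 + r
    t <- sort(round(runif(n, 1, 20), 3))  # distinct times, no ties
    e <- rbinom(n, 1, 0.7)
    if (sum(e) < 2) e[1:2] <- 1
    x <- rnorm(n)
    co <- toy_cohort(t, e, x)
    fit <- fit_cox(co, model_spec("adult", "bmi"))
    b_brute <- cox_pl_brute(t, e, x)
    expect_lt(abs(unname(fit$beta) - b_brute), 1e-3)
  }
})

test_that("duplicating every observation leaves the Breslow fit unchanged", {
  set.seed(32)
  t <- round(runif(12, 1, 20), 2); e <- rbinom(12, 1, 0.7); x <- rnorm(12)
  e[1:2] <- 1
  co <- toy_cohort(t, e, x)
  co2 <- dplyr::bind_rows(co, dplyr::mutate(co, id = paste0(id, "b")))
  f1 <- fit_cox(co, model_spec("adult", "bmi"))
  f2 <- fit_cox(co2, model_spec("adult", "bmi"))
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-8)
})

test_that("null data give a hazard ratio compatible with 1", {
  set.seed(33)
  n <- 500
  t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.6); x <- rnorm(n)  # x independent
  fit <- fit_cox(toy_cohort(t, e, x), model_spec("adult", "bmi"))
  se <- sqrt(diag(fit$covariance))
  expect_lt(abs(unname(fit$beta)), 3 * se)
})

test_that("separation and insufficient events raise explicit errors", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 1, 0, 0, 0)
  x <- c(10, 9, 8, 1, 2, 3)  # perfectly separating covariate
  expect_error(fit_cox(toy_cohort(t, e, x), model_spec("adult", "bmi")),
               class = "pgsrisk_separation")
  expect_error(fit_cox(toy_cohort(t, c(1, 0, 0, 0, 0, 0), x),
                       model_spec("adult", "bmi")),
               class = "pgsrisk_validation")
})

test_that("hazard-ratio tables follow the Wald closed form", {
  set.seed(34)
  co <- toy_cohort(rexp(80, 0.1), rbinom(80, 1, 0.7), rnorm(80))
  fit <- fit_cox(co, model_spec("adult", "bmi"))
  tb <- hr_table(fit)
  se <- sqrt(diag(fit$covariance))
  expect_equal(tb$hr, exp(unname(fit$beta)))
  expect_equal(tb$lo, exp(unname(fit$beta) - qnorm(0.975) * se))
  expect_equal(tb$hi, exp(unname(fit$beta) + qnorm(0.975) * se))
  # CI bounds are exp-symmetric about the HR on the log scale
  expect_equal(log(tb$hr) - log(tb$lo), log(tb$hi) - log(tb$hr),
               tolerance = 1e-10)
  # tidy/glance are consistent with the table
  td <- tidy(fit, exponentiate = TRUE)
  expect_equal(td$estimate, tb$hr)
  expect_equal(glance(fit)$n_events, sum(co$event))
})

test_that("a published-style PS row is reproduced from its CI geometry", {
  # HR 1.27 with 95% CI (1.17, 1.38): the log-scale half-width implies the
  # SE, and the Wald machinery must reproduce the interval and p pattern.
  beta <- log(1.27)
  se <- (log(1.38) - log(1.17)) / (2 * qnorm(0.975))
  expect_equal(exp(beta - qnorm(0.975) * se), 1.17, tolerance = 5e-3)
  expect_equal(exp(beta + qnorm(0.975) * se), 1.38, tolerance = 5e-3)
  p <- 2 * pnorm(-abs(beta / se))
  expect_lt(p, 1e-7)  # strongly significant, matching the reported order
})

test_that("Breslow predicted cumulative incidence matches a hand-computed
           three-observation example", {
  t <- c(2, 4, 6); e <- c(1, 1, 0); x <- c(0.5, -0.5, 0)
  co <- toy_cohort(t, e, x)
  fit <- fit_cox(co, model_spec("adult", "bmi"))
  b <- unname(fit$beta)
  lp <- b * (x - mean(x))
  # Breslow increments at the two event times, by hand
  h1 <- 1 / sum(exp(lp))            # risk set {1,2,3}
  h2 <- 1 / sum(exp(lp[2:3]))       # risk set {2,3}
  expect_equal(fit$baseline$cumhaz, c(h1, h1 + h2), tolerance = 1e-10)
  pred <- predicted_cumulative_incidence(fit, co, 5)
  expect_equal(pred$probability, 1 - exp(-(h1 + h2) * exp(lp)),
               tolerance = 1e-10)
  # horizon before the first event gives probability zero
  pred0 <- predicted_cumulative_incidence(fit, co, 1)
  expect_equal(pred0$probability, rep(0, 3))
  # identical linear predictors give the pooled incidence for everyone
  co_flat <- toy_cohort(t, e, c(1, 1, 1) * 2)
  expect_error(fit_cox(co_flat, model_spec("adult", "bmi")),
               class = "pgsrisk_validation")  # constant covariate: no rank
  # extrapolation beyond the last observed time must be explicit
  expect_error(predicted_cumulative_incidence(fit, co, 100),
               class = "pgsrisk_extrapolation")
  expect_silent(predicted_cumulative_incidence(fit, co, 100,
                                               allow_extrapolation = TRUE))
})

test_that("baseline hazard is monotone and predictions are monotone in
           linear predictor and horizon", {
  set.seed(35)
  co <- toy_cohort(rexp(300, 0.1), rbinom(300, 1, 0.6), rnorm(300))
  fit <- fit_cox(co, model_spec("adult", "bmi"))
  expect_true(all(diff(fit$baseline$cumhaz) >= 0))
  p5 <- predicted_cumulative_incidence(fit, co, 5)
  p9 <- predicted_cumulative_incidence(fit, co, 9)
  expect_true(all(p9$probability >= p5$probability))
  ord <- order(p5$lp)
  expect_true(all(diff(p5$probability[ord]) >= 0))
  expect_true(all(p5$probability >= 0 & p5$probability <= 1))
})

test_that("adding a constant to a covariate changes no hazard ratio", {
  set.seed(36)
  n <- 200
  co <- tibble::tibble(
    id = as.character(1:n), cohort = "adult", baseline_age = rnorm(n, 40, 8),
    sex = sample(c("F", "M"), n, TRUE), followup_time = rexp(n, 0.1),
    event = rbinom(n, 1, 0.6), bmi = rnorm(n, 30, 5), fpg = rnorm(n, 5.4, .4),
    hba1c = rnorm(n, 31, 3), twohpg = rnorm(n, 6, 1.5),
    mother_diab = sample(c("yes", "no", "unknown"), n, TRUE),
    father_diab = sample(c("yes", "no", "unknown"), n, TRUE),
    birthweight_g = NA_real_
  )
  spec <- default_model_spec("adult")
  f1 <- fit_cox(co, spec)
  f2 <- fit_cox(dplyr::mutate(co, bmi = bmi + 100), spec)
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-8)
})

test_that("decile incidence agrees with a hand Kaplan-Meier per group", {
  set.seed(37)
  n <- 20
  t <- round(rexp(n, 0.15), 2); e <- rbinom(n, 1, 0.7); s <- rnorm(n)
  e[1:2] <- 1
  co <- toy_cohort(t, e, s)
  grp <- group_cumulative_incidence(co, s, horizon = 8, n_groups = 2)
  halves <- dplyr::ntile(s, 2)
  for (gi in 1:2) {
    expect_equal(grp$observed[gi],
                 km_brute(t[halves == gi], e[halves == gi], 8),
                 tolerance = 1e-10)
  }
  expect_error(group_cumulative_incidence(co, rep(1, n), 8),
               class = "pgsrisk_degenerate_grouping")
})

test_that("an uninformative score yields coinciding decile curves and a
           perfectly separating score gives extreme deciles", {
  cfg <- sim_config("adult", n_individuals = 5000, n_variants = 10,
                    true_ps_hr_per_sd = 1, covariate_effects = "none",
                    seed = 38)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g, cfg)
  co <- simulate_cohort(g, ss, cfg)
  noise <- with_rng_seed(1, rnorm(nrow(co)))
  grp <- group_cumulative_incidence(co, noise, horizon = 10)
  # standardise every pairwise difference by its Greenwood SE; under the
  # null no pair should exceed the familywise 1% bound for 45 comparisons
  halves <- dplyr::ntile(noise, 10)
  se_g <- sapply(1:10, function(gi) {
    f <- survival::survfit(
      survival::Surv(co$followup_time[halves == gi],
                     co$event[halves == gi]) ~ 1
    )
    i <- findInterval(10, f$time)
    f$surv[i] * f$std.err[i]
  })
  z_max <- max(abs(outer(grp$observed, grp$observed, "-")) /
                 sqrt(outer(se_g^2, se_g^2, "+")))
  expect_lt(z_max, stats::qnorm(1 - 0.01 / 2 / 45))

  # perfectly separating score, no censoring: extremes hit 0 and 1
  t2 <- c(1:10, 101:110); e2 <- rep(1, 20)
  co2 <- toy_cohort(t2, e2, -t2)
  grp2 <- group_cumulative_incidence(co2, -t2, horizon = 50, n_groups = 2)
  expect_equal(grp2$observed[1], 0)
  expect_equal(grp2$observed[2], 1)
})

test_that("calibration is near the identity when the model is true", {
  cfg <- sim_config("adult", n_individuals = 5000, n_variants = 40, seed = 39)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g, cfg)
  co <- simulate_cohort(g, ss, cfg)
  ps <- tibble::tibble(id = co$id, raw = co$ps_true, standardized = co$ps_true)
  spec <- default_model_spec("adult", include_2hpg = TRUE, include_ps = TRUE)
  fit <- fit_cox(co, spec, ps)
  pred <- predicted_cumulative_incidence(fit, co, 10, ps)
  bins <- calibration_bins(pred, co)
  slope <- stats::coef(stats::lm(observed ~ mean_predicted, data = bins,
                                 weights = bins$n))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  # bin means conserve the pooled mean prediction
  expect_equal(sum(bins$mean_predicted * bins$n) / sum(bins$n),
               mean(pred$probability), tolerance = 1e-10)
  # constant predictions collapse to a single bin with a warning
  flat <- dplyr::mutate(pred, probability = 0.3)
  expect_warning(cb <- calibration_bins(flat, co), "single")
  expect_equal(nrow(cb), 1)
})

test_that("risk surface is monotone in both genetic and clinical risk", {
  cfg <- sim_config("adult", n_individuals = 1200, n_variants = 30, seed = 40)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g, cfg)
  co <- simulate_cohort(g, ss, cfg)
  ps <- tibble::tibble(id = co$id, raw = co$ps_true, standardized = co$ps_true)
  fit <- fit_cox(co, default_model_spec("adult", include_ps = TRUE), ps)
  surf <- predicted_risk_surface(fit, co, 10, ps)
  by_pct <- split(surf, surf$clinical_percentile)
  for (s in by_pct) expect_true(all(diff(s$probability) > 0))
  by_ps <- split(surf, surf$ps_value)
  for (s in by_ps) expect_true(all(diff(s$probability) > 0))
})
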