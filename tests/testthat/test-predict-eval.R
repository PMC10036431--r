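# Discrimination, reclassification and decision-analytic metrics.

test_that("status at the horizon follows the event/nonevent/excluded rule", {
  co <- toy_cohort(c(9, 4, 12, 10, 10, 11), c(1, 0, 1, 1, 0, 0), rnorm(6))
  st <- status_at_horizon(co, 10)
  expect_equal(as.character(st$status),
               c("event", "excluded", "nonevent", "event", "nonevent",
                 "nonevent"))
  # 12-person toy against hand classification
  t <- c(1, 2, 3, 9.5, 10, 10.5, 11, 4, 6, 15, 20, 0.5)
  e <- c(1, 1, 0, 1, 1, 1, 0, 0, 1, 0, 1, 0)
  hand <- ifelse(e == 1 & t <= 10, "event",
                 ifelse(t >= 10, "nonevent", "excluded"))
  st2 <- status_at_horizon(toy_cohort(t, e, rnorm(12)), 10)
  expect_equal(as.character(st2$status), hand)
  expect_error(status_at_horizon(co, 0), class = "pgsrisk_invalid_config")
})

test_that("Harrell's C equals exhaustive pair enumeration on censored data", {
  set.seed(51)
  for (r in 1:30) {
    n <- sample(10:60, 1)
    t <- round(rexp(n, 0.2), 1)
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    s <- sample(1:6, n, replace = TRUE)  # many score ties
    res <- concordance_index(t, e, s)
    brute <- harrell_brute(t, e, s)
    expect_identical(res$c_statistic, unname(brute["c"]))
    expect_identical(res$n_usable_pairs, unname(brute["usable"]))
    expect_equal(res$n_concordant + res$n_discordant + res$n_tied,
                 res$n_usable_pairs)
  }
})

test_that("perfect discrimination gives C = 1 and a constant score 0.5", {
  t <- 1:10; e <- rep(1, 10)
  expect_equal(concordance_index(t, e, -t)$c_statistic, 1)
  expect_equal(concordance_index(t, e, rep(2, 10))$c_statistic, 0.5)
})

test_that("concordance confidence intervals behave and are reproducible", {
  set.seed(52)
  t <- rexp(150, 0.2); e <- rbinom(150, 1, 0.6); s <- rnorm(150) - t / 10
  a <- concordance_index(t, e, s, ci = "asymptotic")
  expect_true(a$ci95[1] < a$c_statistic && a$c_statistic < a$ci95[2])
  b1 <- concordance_index(t, e, s, ci = "bootstrap", n_boot = 100, seed = 4)
  b2 <- concordance_index(t, e, s, ci = "bootstrap", n_boot = 100, seed = 4)
  expect_identical(b1$ci95, b2$ci95)
})

test_that("delta AUC arithmetic and the identity comparison", {
  expect_equal(auc_difference(0.728, 0.735), 0.007, tolerance = 1e-9)
  set.seed(53)
  co <- toy_cohort(rexp(150, 0.1), rbinom(150, 1, 0.6), rnorm(150))
  fit <- fit_cox(co, model_spec("adult", "bmi"))
  cmp <- compare_auc(fit, fit, co, n_boot = 100, seed = 1)
  expect_identical(cmp$delta_auc, 0)
  expect_equal(cmp$p, 1)
})

test_that("delta AUC under the null never rejects above the nominal rate", {
  set.seed(54)
  n <- 1000
  pvals <- replicate(200, {
    t <- rexp(n, 0.1)
    e <- rbinom(n, 1, 0.6)
    x <- rnorm(n) + 0.5 * t  # informative base covariate
    noise <- rnorm(n)        # added predictor carries no signal
    co <- tibble::tibble(
      id = sprintf("p%04d", 1:n), cohort = "adult", baseline_age = 40,
      sex = "F", followup_time = t, event = e, bmi = x, fpg = noise,
      hba1c = 30, twohpg = 6, mother_diab = "no", father_diab = "no",
      birthweight_g = NA_real_
    )
    base <- fit_cox(co, model_spec("adult", "bmi"))
    full <- fit_cox(co, model_spec("adult", c("bmi", "fpg")))
    cmp <- compare_auc(base, full, co, n_boot = 200,
                       seed = sample.int(1e6, 1))
    cmp$p
  })
  # the Wald-on-paired-bootstrap test for nested models is conservative:
  # it must not exceed the nominal rate, and p-values must not collapse
  expect_lte(mean(pvals < 0.05), 0.09)
  expect_gt(stats::median(pvals), 0.10)
})

test_that("continuous NRI components compose and match hand enumeration", {
  # 6-person toy, 3 events: 2 events up / 1 down; 2 nonevents down / 1 up
  base <- tibble::tibble(id = letters[1:6], horizon = 10,
                         probability = rep(0.3, 6), model_label = "base")
  full <- dplyr::mutate(base,
                        probability = c(0.4, 0.5, 0.2, 0.1, 0.2, 0.6),
                        model_label = "full")
  status <- tibble::tibble(
    id = letters[1:6],
    status = factor(c("event", "event", "event",
                      "nonevent", "nonevent", "nonevent"),
                    levels = c("event", "nonevent", "excluded"))
  )
  nri <- continuous_nri(base, full, status)
  expect_equal(nri$event_component, 1 / 3)
  expect_equal(nri$nonevent_component, 1 / 3)
  expect_equal(nri$total, 2 / 3)
  expect_equal(nri$total, nri$event_component + nri$nonevent_component,
               tolerance = 1e-12)
  # identical predictions give exactly zero
  expect_warning(nri0 <- continuous_nri(base, base, status), "tied")
  expect_identical(nri0$total, 0)
})

test_that("published component pairs compose to the published totals", {
  # construct cohorts whose up/down counts yield the reported components
  mk <- function(n_ev, up_ev, down_ev, n_ne, down_ne, up_ne) {
    n <- n_ev + n_ne
    ids <- sprintf("i%04d", seq_len(n))
    delta <- c(rep(0.1, up_ev), rep(-0.1, down_ev),
               rep(0, n_ev - up_ev - down_ev),
               rep(-0.1, down_ne), rep(0.1, up_ne),
               rep(0, n_ne - down_ne - up_ne))
    base <- tibble::tibble(id = ids, horizon = 10, probability = 0.5,
                           model_label = "base")
    full <- dplyr::mutate(base, probability = 0.5 + delta,
                          model_label = "full")
    status <- tibble::tibble(
      id = ids,
      status = factor(rep(c("event", "nonevent"), c(n_ev, n_ne)),
                      levels = c("event", "nonevent", "excluded"))
    )
    continuous_nri(base, full, status)
  }
  adult <- mk(1000, 546, 454, 1000, 589, 411)
  expect_equal(adult$event_component, 0.092)
  expect_equal(adult$nonevent_component, 0.178)
  expect_equal(adult$total, 0.270, tolerance = 1e-12)
  youth <- mk(1000, 542, 457, 1000, 591, 408)
  expect_equal(youth$total, 0.085 + 0.183, tolerance = 1e-12)
  birth <- mk(1000, 553, 447, 1000, 628, 372)
  expect_equal(birth$total, 0.106 + 0.256, tolerance = 1e-12)
})

test_that("NRI bootstrap CI is deterministic and equals the stored
           replicate quantiles", {
  set.seed(55)
  n <- 300
  co <- toy_cohort(rexp(n, 0.08), rbinom(n, 1, 0.6), rnorm(n))
  base <- tibble::tibble(id = co$id, horizon = 10,
                         probability = stats::runif(n), model_label = "b")
  full <- dplyr::mutate(base, probability = probability +
                          stats::rnorm(n, 0, 0.05))
  ci1 <- nri_bootstrap_ci(base, full, co, 10, n_boot = 100, seed = 8)
  ci2 <- nri_bootstrap_ci(base, full, co, 10, n_boot = 100, seed = 8)
  expect_identical(ci1$ci95, ci2$ci95)
  vals <- attr(ci1, "boot_values")
  expect_equal(ci1$ci95, unname(stats::quantile(vals, c(0.025, 0.975))))
  expect_error(nri_bootstrap_ci(base, full, co, 10, n_boot = 50),
               class = "pgsrisk_invalid_config")
})

test_that("per-predictor NRI: structure, null predictor, redundant predictor", {
  cfg <- sim_config("adult", n_individuals = 3000, n_variants = 20,
                    covariate_effects = c(twohpg = 0), seed = 56)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g, cfg)
  co <- simulate_cohort(g, ss, cfg)
  spec <- default_model_spec("adult", include_2hpg = TRUE)
  tab <- per_predictor_nri(co, spec, 10)
  expect_equal(tab$term, spec$covariates)  # one row per block
  # 2hPG has no generative effect here: its NRI sits near zero
  expect_lt(abs(tab$nri[tab$term == "twohpg"]), 0.06)

  # a predictor that duplicates another (up to negligible noise) adds
  # nothing: its NRI is about zero
  co2 <- dplyr::mutate(co, twohpg = fpg + stats::rnorm(nrow(co), 0, 0.1))
  tab2 <- per_predictor_nri(co2, model_spec("adult", c("fpg", "twohpg")), 10)
  expect_lt(abs(tab2$nri[tab2$term == "twohpg"]), 0.06)
})

test_that("net benefit matches the hand-computed toy and its limits", {
  # n = 10, no censoring; 5 selected of whom 3 are events by the horizon
  t <- c(5, 6, 7, 15, 16, 20, 21, 22, 23, 24)
  e <- rep(1, 10)
  co <- toy_cohort(t, e, rnorm(10))
  pred <- tibble::tibble(id = co$id, horizon = 10,
                         probability = c(rep(0.9, 5), rep(0.1, 5)),
                         model_label = "m")
  expect_equal(net_benefit(pred, co, 10, 0.2),
               3 / 10 - (2 / 10) * (0.2 / 0.8))
  # selecting nobody gives zero by convention
  expect_message(nb0 <- net_benefit(pred, co, 10, 0.95), "No individual")
  expect_identical(nb0, 0)
  # as pt -> 0 with everyone selected, net benefit -> overall KM incidence
  km <- km_brute(t, e, 10)
  expect_equal(net_benefit(pred, co, 10, 1e-6), km, tolerance = 1e-4)
  expect_error(net_benefit(pred, co, 10, 1.2), class = "pgsrisk_invalid_config")
})

test_that("decision curves honour treat-none/treat-all identities and
           model dominance by the oracle", {
  set.seed(57)
  t <- round(rexp(40, 0.1), 1); e <- rep(1, 40)
  co <- toy_cohort(t, e, rnorm(40))
  truth <- as.numeric(t <= 10)
  oracle <- tibble::tibble(id = co$id, horizon = 10, probability = truth,
                           model_label = "oracle")
  other <- tibble::tibble(id = co$id, horizon = 10,
                          probability = stats::runif(40), model_label = "x")
  dc <- decision_curve(list(oracle = oracle, other = other), co, 10,
                       pt_grid = seq(0.05, 0.6, by = 0.05))
  tn <- dplyr::filter(dc, model == "treat_none")
  expect_true(all(tn$net_benefit == 0))
  # treat-all equals the KM incidence as pt -> 0
  dc0 <- decision_curve(list(oracle = oracle), co, 10, pt_grid = c(1e-6, 0.5))
  ta <- dplyr::filter(dc0, model == "treat_all")
  expect_equal(ta$net_benefit[1], km_brute(t, e, 10), tolerance = 1e-4)
  # the oracle model dominates any other at every threshold (no censoring)
  for (pt in unique(dc$pt)) {
    nb_o <- dc$net_benefit[dc$model == "oracle" & dc$pt == pt]
    nb_x <- dc$net_benefit[dc$model == "other" & dc$pt == pt]
    expect_gte(nb_o + 1e-12, nb_x)
  }
  # identical models give identical curves
  dc2 <- decision_curve(list(a = other, b = other), co, 10,
                        pt_grid = seq(0.1, 0.5, 0.1))
  wide <- tidyr::pivot_wider(dc2[, c("pt", "model", "net_benefit")],
                             names_from = "model",
                             values_from = "net_benefit")
  expect_identical(wide$a, wide$b)
  # proportion selected is non-increasing in pt
  for (m in unique(dc$model)) {
    ps <- dc$proportion_selected[dc$model == m]
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("an informative score improves mid-range net benefit on
           synthetic cohorts", {
  cfg <- sim_config("adult", n_individuals = 5000, n_variants = 40,
                    true_ps_hr_per_sd = 1.8, seed = 58)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g, cfg)
  co <- simulate_cohort(g, ss, cfg)
  ps <- tibble::tibble(id = co$id, raw = co$ps_true, standardized = co$ps_true)
  clin <- fit_cox(co, default_model_spec("adult"))
  full <- fit_cox(co, default_model_spec("adult", include_ps = TRUE), ps)
  pred_c <- predicted_cumulative_incidence(clin, co, 10)
  pred_f <- predicted_cumulative_incidence(full, co, 10, ps)
  dc <- decision_curve(list(clinical = pred_c, with_ps = pred_f), co, 10)
  imp <- nb_improvement(dc, "clinical", "with_ps")
  mid <- dplyr::filter(imp, pt >= 0.2, pt <= 0.45)
  expect_true(all(mid$absolute > -0.005))
  expect_gt(mean(mid$absolute), 0)
})
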