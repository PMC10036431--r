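# Bootstrap comparison of polygenic-score hazard ratios between
# overlapping cohorts: persons (not rows) are the resampling unit, so a
# person contributing to several cohorts is jointly in or out of a
# replicate and the cross-cohort dependence is preserved.

#' Bootstrap test for differences in PS hazard ratios between cohorts
#'
#' Fits the unadjusted Cox association of the standardised polygenic
#' score in each cohort, then resamples persons with replacement
#' (`n_boot` times); each sampled person contributes all their cohort
#' rows with their multiplicity. Per replicate the per-cohort log hazard
#' ratios are refit, and for each unordered cohort pair the bootstrap
#' standard error of the log-HR difference yields a two-sided Wald test
#' of the observed difference.
#'
#' @param cohorts Named list of cohort tibbles (or a single tibble with a
#'   `cohort` column).
#' @param membership Tibble `id`, `cohort` covering every cohort row.
#' @param ps Standardised polygenic-score tibble covering all ids; the
#'   original (replicate-invariant) standardisation is used throughout.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param p_method `"wald"` (default: normal test of delta over the
#'   bootstrap SE) or `"percentile"` (two-sided percentile p of the
#'   centred bootstrap distribution).
#' @return A `cohort_comparison` tibble: one row per unordered pair with
#'   `cohort_a`, `cohort_b`, `log_hr_a`, `log_hr_b`, `delta_log_hr`,
#'   `se`, `p`, `n_boot`, `n_dropped`; per-cohort HRs in the
#'   `"per_cohort"` attribute.
#' @export
bootstrap_hr_difference <- function(cohorts, membership, ps, n_boot = 2000,
                                    seed = 1L,
                                    p_method = c("wald", "percentile")) {
  p_method <- match.arg(p_method)
  if (is.data.frame(cohorts)) {
    cohorts <- split(cohorts, cohorts$cohort)
  }
  labels <- names(cohorts)
  for (lab in labels) {
    if (sum(cohorts[[lab]]$event) < 2) {
      stop_pgs(paste0("Cohort '", lab, "' has fewer than 2 events."),
               "pgsrisk_validation")
    }
    if (!all(cohorts[[lab]]$id %in% membership$id)) {
      stop_pgs("Membership map does not cover all cohort rows.",
               "pgsrisk_validation")
    }
  }
  persons <- sort(unique(membership$id))
  n_persons <- length(persons)
  score <- ps$standardized[match(persons, ps$id)]
  if (anyNA(score)) {
    stop_pgs("Polygenic score does not cover every person.",
             "pgsrisk_validation")
  }
  # Pre-extract per-cohort vectors indexed against the person registry.
  dat <- lapply(cohorts, function(co) {
    list(time = co$followup_time, event = co$event,
         score = ps$standardized[match(co$id, ps$id)],
         person = match(co$id, persons))
  })
  obs <- vapply(dat, function(d) {
    unname(fast_cox1(d$time, d$event, d$score)["beta"])
  }, numeric(1))

  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(labels),
                 dimnames = list(NULL, labels))
  with_rng_seed(seed, {
    for (b in seq_len(n_boot)) {
      counts <- tabulate(sample.int(n_persons, n_persons, replace = TRUE),
                         nbins = n_persons)
      ok <- TRUE
      est <- numeric(length(labels))
      for (k in seq_along(labels)) {
        d <- dat[[k]]
        w <- counts[d$person]
        keep <- w > 0
        if (sum(d$event[keep] * w[keep]) < 2 ||
            length(unique(d$score[keep])) < 2) {
          ok <- FALSE
          break
        }
        est[k] <- fast_cox1(d$time, d$event, d$score, weights = w)["beta"]
      }
      if (ok) boot[b, ] <- est
    }
  })
  complete <- stats::complete.cases(boot)
  n_dropped <- sum(!complete)
  if (n_dropped > 0.05 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates dropped (degenerate resample).",
                 n_dropped, n_boot))
  }
  boot <- boot[complete, , drop = FALSE]
  pairs <- utils::combn(labels, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    delta <- obs[a] - obs[b]
    dist <- boot[, a] - boot[, b]
    se <- sd(dist)
    p <- if (!is.finite(se) || se == 0) {
      if (abs(delta) < 1e-15) 1 else 0
    } else if (p_method == "wald") {
      2 * pnorm(-abs(delta / se))
    } else {
      centred <- dist - mean(dist)
      max(2 * min(mean(centred >= abs(delta)), mean(centred <= -abs(delta))),
          1 / (length(dist) + 1))
    }
    tibble(cohort_a = a, cohort_b = b,
           log_hr_a = unname(obs[a]), log_hr_b = unname(obs[b]),
           delta_log_hr = unname(delta), se = se, p = min(p, 1),
           n_boot = nrow(boot), n_dropped = n_dropped)
  })
  structure(out,
            per_cohort = tibble(cohort = labels, log_hr = unname(obs),
                                hr = exp(unname(obs))),
            seed = seed,
            class = c("cohort_comparison", class(out)))
}
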