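# pgsrisk

Does a polygenic score (PS) add anything to ordinary clinical variables
when predicting who will develop a disease? `pgsrisk` implements the
full evaluation chain for that question in incident type 2 diabetes
cohorts — but the machinery is generic to any censored binary-outcome
setting:

* **Score construction** from GWAS summary statistics: allele
  harmonisation to a dosage panel, MAF/imputation-quality filters,
  pruning-and-thresholding selection of independent genome-wide
  significant variants, the weighted allele sum
  `PS_i = Σ_v dosage_iv · log(OR_v)`, standardisation to mean 0 / SD 1
  across the study population, cross-validated population-specific
  weights and variant sets, and principal-component residualisation.
* **Survival modelling**: Cox proportional hazards (Breslow ties) with
  an explicit Breslow baseline cumulative hazard, giving per-person
  predicted cumulative incidence
  `1 − exp(−H0(h)·exp(βᵀ(x − x̄)))` at a fixed horizon `h`
  (10 years for cohorts recruited in adulthood or youth, 30 years for
  a birth cohort).
* **Increment metrics**: Harrell's C (the fixed-horizon AUC) and its
  paired-bootstrap difference ΔAUC; continuous net reclassification
  improvement (event + nonevent components) with bootstrap CIs;
  decision-curve net benefit
  `x·F − x·(1−F)·pt/(1−pt)` across threshold probabilities, with
  treat-all/treat-none references.
* **Cross-cohort comparison**: a person-level bootstrap (individuals
  appearing in several overlapping cohorts are resampled jointly) for
  differences in the unadjusted PS log hazard ratio between cohorts.
* **Synthetic cohorts**: a generator producing genotypes, discovery
  summary statistics, clinical covariates and censored event times with
  the proportional-hazards structure the analysis assumes, including
  three overlapping age cohorts — so everything above is testable
  without restricted data.

## Worked example

```r
library(pgsrisk)
library(dplyr)

cfg    <- sim_config("adult", seed = 1)          # 2333 people, 300 variants
geno   <- simulate_genotypes(cfg)
stats  <- simulate_summary_stats(geno, cfg)
cohort <- simulate_cohort(geno, stats, cfg)

geno_qc <- qc_filter(geno)                        # MAF ≥ 0.01, info ≥ 0.5
harm    <- harmonize(select(stats, -beta_true), geno_qc)
sel     <- select_variants_pt(harm$stats, geno_qc)  # p<5e-8, 500kb, r²≤0.1
ps      <- standardize_ps(compute_ps(geno_qc, sel, weight_source = "PT"))

fit_clin <- fit_cox(cohort, default_model_spec("adult"))
fit_full <- fit_cox(cohort, default_model_spec("adult", include_ps = TRUE), ps)
filter(hr_table(fit_full), term == "ps")
#> # A tibble: 1 × 5
#>   term     hr    lo    hi            p
#>   <chr> <dbl> <dbl> <dbl>        <dbl>
#> 1 ps     1.24  1.15  1.34 0.0000000131

cmp <- compare_auc(fit_clin, fit_full, cohort, ps, n_boot = 500, seed = 1)
#> AUC clinical 0.698, with PS 0.707, dAUC 0.0094 (p = 0.00761)

pred_c <- predicted_cumulative_incidence(fit_clin, cohort, 10)
pred_f <- predicted_cumulative_incidence(fit_full, cohort, 10, ps)
nri_bootstrap_ci(pred_c, pred_f, cohort, 10, n_boot = 1000, seed = 1)
#> <nri_result> NRI = 0.2106 (events 0.1239 + nonevents 0.0866);
#>   573 ev / 554 non-ev / 1206 excluded
#>   95% CI (0.0935, 0.3294)
```

Read: the score, built by pruning-and-thresholding from the simulated
discovery GWAS, carries a hazard ratio of 1.24 per SD *after*
adjustment for the clinical model; it moves the 10-year AUC from 0.698
to 0.707 (a modest ΔAUC of 0.009, as typically seen for single added
predictors), yet reclassifies a net 21% of people in the correct
direction — the usual pattern in which NRI reveals an individual-level
contribution that ΔAUC understates. Decision curves
(`decision_curve()`, `autoplot()`) then show at which intervention
thresholds that contribution translates into net clinical benefit.

The end-to-end pipeline — three overlapping cohorts, scoring, fitting,
all metrics, the cross-cohort comparison, and a reproducibility
manifest — is one call:

```r
res <- run_pipeline(run_config(simulation = list(), seed = 1), "results-dir")
```

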