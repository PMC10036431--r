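---
title: "Evaluating a polygenic score added to clinical risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a polygenic score added to clinical risk models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pgsrisk asks a concrete epidemiological question: *how much does a
polygenic score (PS) add to ordinary clinical variables when predicting
who will develop a disease — here, type 2 diabetes — over a fixed
follow-up horizon?* The package implements the complete evaluation
chain: score construction from GWAS summary statistics, Cox modelling
with an explicit baseline hazard, and the discrimination,
reclassification and decision-analytic metrics that quantify the
increment, together with a synthetic-cohort generator so every stage is
testable without access to any restricted cohort data.

## The model

Each cohort is analysed with a Cox proportional-hazards model

$$\lambda(t \mid x_i) = \lambda_0(t)\, e^{\beta^\top x_i},$$

where $x_i$ collects the clinical covariates (age per decade, sex,
parental diabetes as yes/no/unknown indicators per parent, adiposity,
fasting glucose, HbA1c, optionally 2-hour glucose, and dichotomised
birthweight in the birth cohort) and, in the augmented model, the
standardised PS. The PS is a weighted allele sum
$\mathrm{PS}_i = \sum_v d_{iv} \hat\beta_v$ over variants selected by
pruning and thresholding from discovery GWAS summary statistics, with
$d_{iv} \in [0,2]$ the effect-allele dosage; it is z-scored across the
entire study population so hazard ratios are per SD. Predicted
cumulative incidence by horizon $h$ uses the Breslow step-function
baseline cumulative hazard $\hat H_0$:

$$\hat P_i(h) = 1 - \exp\{-\hat H_0(h)\, e^{\hat\beta^\top (x_i - \bar x)}\}.$$

The increment from the PS is quantified three ways:

* **Discrimination.** Harrell's C (equal to the fixed-horizon ROC AUC
  in this setting) for the clinical and the clinical+PS model, and
  their difference with a paired person-level bootstrap.
* **Reclassification.** Continuous net reclassification improvement:
  the net proportion of events assigned a higher predicted probability
  by the augmented model plus the net proportion of nonevents assigned
  a lower one, with percentile bootstrap confidence intervals. Status
  at the horizon is *event*, *nonevent*, or *excluded* (censored before
  the horizon). Exact prediction ties count as no reclassification.
* **Decision analysis.** Net benefit at threshold probability $p_t$,
  $x F - x(1-F)\,p_t/(1-p_t)$ with $x$ the selected fraction and $F$
  the Kaplan–Meier event probability by the horizon among the selected
  (the survival extension of decision-curve analysis), against
  treat-all and treat-none references.

Cross-cohort differences in the unadjusted PS log hazard ratio are
tested by resampling *persons* (not rows) with replacement, so an
individual contributing to several overlapping cohorts is jointly in or
out of each replicate; the bootstrap SD of the log-HR difference feeds
a two-sided Wald test.

## What the synthetic-data generator emulates

`sim_config()` fixes the study conditions once per cohort design:

| design | n | true PS HR/SD | baseline scale (y) | dropout /y | max follow-up | horizon |
|--------|------|------|-----|------|----|----|
| adult | 2333 | 1.31 | 28 | 0.10 | 25 y | 10 y |
| youth | 2229 | 1.59 | 95 | 0.11 | 25 y | 10 y |
| birth | 2894 | 1.47 | 104 | 0.03 | 45 y | 30 y |

The cohort sizes, per-SD hazard ratios, event fractions over the
analysis horizon and person-years per participant match the published
descriptors of the three age cohorts the package is modelled on; the
baseline is exponential (Weibull shape 1) with the scale solved from
the reported 10- or 30-year cumulative incidence. Clinical covariate
*effects* (log hazard ratios) are taken from the published adjusted
models, including the U-shaped birthweight risk (elevated below 3000 g
and above 4000 g). Covariate *marginal distributions* are package
choices — normal adiposity and glycaemia with plausible means and
correlations, parental status yes/no/unknown with fixed probabilities —
because only the hazard-model structure, not the marginals, matters
for validating the methods. Genotypes are Hardy–Weinberg binomial
dosages at uniform MAF, optionally beta-perturbed into continuous
dosages to exercise the imputation-quality filter; info scores are
Beta(14, 1) (median about 0.95). Summary statistics follow the standard
GWAS error model with SE $1/\sqrt{2Np(1-p)}$.

Overlapping cohorts share one person registry (default overlap 0.59,
giving roughly 4770 distinct persons for 7456 cohort rows). A person's
event and censoring uniforms are drawn once and transformed through
each cohort's own baseline, so outcomes for the same person observed
from different baselines are strongly positively dependent — the
dependence the person-level bootstrap exists to handle — while each
cohort marginally obeys its configured proportional-hazards law. The
real study's dropout process and cross-cohort dependence are not
published; exponential dropout and comonotone coupling are this
package's modelling choices. Consequently, passing tests demonstrate
correctness of the estimators and calibration of the resampling
procedures under a faithful proportional-hazards world, not robustness
to real-data features such as secular trends, family structure,
linkage disequilibrium or informative censoring, none of which are
simulated.

## Numerical and design choices

* **Ties and baseline.** Breslow tie handling (matching the Breslow
  baseline; the software used for the original analyses defaults to
  it); Efron is available via `ties = "efron"`. The baseline hazard is
  computed at covariate means; predictions are invariant to that
  centring.
* **Pruning and thresholding.** Defaults $p < 5\times 10^{-8}$,
  window 500 kb, $r^2 \le 0.1$, all configurable; ties in p-value break
  by genomic position then allele order, so selection is independent of
  record order. The published analyses do not state their window or
  $r^2$; these are standard practice values.
* **Harmonisation.** Variants match on chromosome and position; effect
  sizes are re-signed when the counted allele differs; palindromic
  variants with effect-allele frequency within 0.08 of 0.5 are dropped
  as strand-ambiguous (a convention, configurable).
* **Cross-validated scores.** Out-of-fold weights use unadjusted
  per-variant logistic regressions of the event indicator on dosage
  (log-OR weights, matching the convention of external GWAS weights);
  a per-variant Cox option exists. The published population-specific
  scores do not state the per-variant model; logistic is the default
  here and the choice is exposed.
* **NRI exclusions.** Persons censored before the horizon are excluded
  from NRI classification (the simplest defensible reading of
  classifying events and nonevents at a fixed follow-up); an
  IPCW-style alternative was considered out of scope. A person censored
  exactly at the horizon counts as a nonevent.
* **ΔAUC inference.** Paired bootstrap (resampling individuals once per
  replicate, re-evaluating both models' linear predictors; refitting is
  optional). For *nested* models under the null this Wald-on-bootstrap
  construction is conservative — in simulation at n = 1000 it rejects
  at well below the nominal 5% — so its p-values are trustworthy but
  not sharp; the identity comparison returns p = 1 by convention.
* **Cross-cohort test.** Wald z on the bootstrap SE by default (a
  percentile p is available); the PS keeps its original, replicate-
  invariant standardisation inside replicates. Replicates in which a
  cohort loses all its events are dropped and counted, with a warning
  above 5%.
* **Degenerate inputs.** Zero-variance scores, rank-deficient designs
  (including constant covariates, which a Cox model cannot identify),
  separation (diverging coefficients), folds without events, empty
  risk-score groups and horizons beyond observed follow-up all raise
  classed errors rather than silently proceeding.

## Problem sizes used in the automated checks

The test-suite simulations use the smallest sizes at which each
property is informative: parameter recovery runs 200 replicates of
n = 2500 adult-like cohorts at a true PS HR of 1.30/SD; null
calibration uses n = 2000 cohorts (50 repeats for NRI interval
coverage) and 100 repeats of paired n = 1500 overlapping cohorts at
n_boot = 500 for the type-I error of the cross-cohort test; oracle
equivalence checks run on 100 random censored datasets of up to 200
individuals. The acceptance script runs the full pipeline at the
default design sizes above.

## Known limitations

* No LD structure beyond optional correlated toys; no LD-aware
  shrinkage scores (the score construction deliberately uses selected
  genome-wide-significant variants only).
* No competing risks, time-varying covariates, frailty or left
  truncation; no proportional-hazards diagnostics.
* Categorical (risk-stratum) NRI and integrated discrimination
  improvement are out of scope.
* The generator's covariate marginals are stylised; do not use it to
  study marginal-distribution-sensitive questions.

## A minimal run

```{r, eval = FALSE}
library(pgsrisk)

config <- run_config(
  simulation = list(designs = c("adult", "youth", "birth"), overlap = 0.59),
  seed = 1
)
res <- run_pipeline(config, out_dir = "pgsrisk-results")
res$metrics                      # AUC, delta AUC, NRI, HR per SD by cohort
res$comparison                   # pairwise cross-cohort HR differences
autoplot(res$evals$adult$decision)
```
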