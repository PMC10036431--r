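# End-to-end orchestration: simulate (or load) -> score -> fit ->
# evaluate -> decision curves -> cross-cohort comparison, with a
# machine-readable manifest so a rerun with the same configuration
# reproduces every output byte-for-byte.

#' Build a pipeline run configuration
#'
#' Exactly one of `simulation` and `inputs` must be supplied.
#'
#' @param simulation List describing the synthetic study: `designs`
#'   (cohort designs to simulate; default all three), `overlap` (fraction
#'   shared between cohorts), `n_variants`, and optional per-design
#'   overrides passed to [sim_config()].
#' @param inputs List of paths: `genotypes` (+ `genotype_format`),
#'   `summary_stats`, `phenotypes`.
#' @param horizons Named vector of per-cohort prediction horizons in
#'   years (defaults: adult 10, youth 10, birth 30).
#' @param metrics List of evaluation settings: `n_boot_nri`,
#'   `n_boot_auc`, `n_boot_hr`, `pt_grid`.
#' @param ps_method Variant-selection for the score: currently
#'   `"pt"` (pruning and thresholding) with settings `p_threshold`,
#'   `window_bp`, `r2_max`.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` object.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       horizons = c(adult = 10, youth = 10, birth = 30),
                       metrics = list(), ps_method = list(), seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop_pgs("Supply exactly one of `simulation` and `inputs`.",
             "pgsrisk_invalid_config")
  }
  if (any(horizons <= 0)) {
    stop_pgs("Horizons must be positive.", "pgsrisk_invalid_config")
  }
  metrics <- modifyList(
    list(n_boot_nri = 1000, n_boot_auc = 500, n_boot_hr = 2000,
         pt_grid = seq(0.01, 0.60, by = 0.01)),
    metrics
  )
  ps_method <- modifyList(
    list(p_threshold = 5e-8, window_bp = 5e5, r2_max = 0.1),
    ps_method
  )
  if (!is.null(simulation)) {
    simulation <- modifyList(
      list(designs = c("adult", "youth", "birth"), overlap = 0.59),
      simulation
    )
  }
  structure(list(simulation = simulation, inputs = inputs,
                 horizons = horizons, metrics = metrics,
                 ps_method = ps_method, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    overrides <- sim[setdiff(names(sim), c("designs", "overlap"))]
    cfgs <- lapply(sim$designs, function(d) {
      do.call(sim_config, c(list(cohort_design = d,
                                 seed = derive_seed(config$seed, 21L)),
                            overrides))
    })
    res <- simulate_overlapping_cohorts(cfgs, overlap = sim$overlap,
                                        seed = derive_seed(config$seed, 22L))
    stats <- dplyr::select(res$sumstats, -"beta_true")
    list(genotypes = res$genotypes, sumstats = stats,
         cohorts = res$cohorts, membership = res$membership)
  } else {
    geno <- read_dosages(config$inputs$genotypes,
                         format = config$inputs$genotype_format %||% "tsv")
    stats <- read_summary_stats(config$inputs$summary_stats)
    pheno <- read_phenotypes(config$inputs$phenotypes)
    cohorts <- split(pheno, pheno$cohort)
    list(genotypes = geno, sumstats = stats, cohorts = cohorts,
         membership = dplyr::distinct(
           dplyr::select(pheno, "id", "cohort")))
  }
}

#' Run the full evaluation pipeline
#'
#' Executes, per the configuration: data simulation or loading; genotype
#' QC and allele harmonisation; pruning-and-thresholding variant
#' selection; polygenic-score computation and standardisation over the
#' whole study population; per-cohort Cox fits (clinical and
#' clinical + PS); predicted cumulative incidence at the cohort horizon;
#' AUC comparison, NRI with bootstrap CI, calibration and decision
#' curves; and the cross-cohort bootstrap comparison of unadjusted PS
#' hazard ratios. All tabular results are written to `out_dir` together
#' with a manifest (seed, configuration hash, file checksums).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted objects and result tables
#'   (`metrics`, `hr_tables`, `decision_curves`, `comparison`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pgs(paste0("Pipeline stage '", name, "' failed: ",
                      conditionMessage(e)), "pgsrisk_pipeline")
    })
  }

  inp <- stage("inputs", pipeline_inputs(config))

  score <- stage("score", {
    geno_qc <- qc_filter(inp$genotypes)
    harm <- harmonize(inp$sumstats, geno_qc)
    sel <- select_variants_pt(
      harm$stats, geno_qc,
      p_threshold = config$ps_method$p_threshold,
      window_bp = config$ps_method$window_bp,
      r2_max = config$ps_method$r2_max
    )
    ps <- standardize_ps(compute_ps(geno_qc, sel, weight_source = "PT"))
    list(ps = ps, harm_report = harm$report, n_selected = nrow(sel))
  })
  ps <- score$ps

  evaluate_cohort <- function(cohort, label) {
    horizon <- unname(config$horizons[label])
    if (is.na(horizon)) {
      stop_pgs(paste0("No horizon configured for cohort '", label, "'."),
               "pgsrisk_invalid_config")
    }
    spec_clin <- default_model_spec(label)
    spec_full <- default_model_spec(label, include_ps = TRUE)
    fit_clin <- fit_cox(cohort, spec_clin)
    fit_full <- fit_cox(cohort, spec_full, ps)
    pred_clin <- predicted_cumulative_incidence(fit_clin, cohort, horizon,
                                                label = "clinical")
    pred_full <- predicted_cumulative_incidence(fit_full, cohort, horizon, ps,
                                                label = "clinical+PS")
    auc <- compare_auc(fit_clin, fit_full, cohort, ps,
                       n_boot = config$metrics$n_boot_auc,
                       seed = derive_seed(config$seed, 31L))
    nri <- nri_bootstrap_ci(pred_clin, pred_full, cohort, horizon,
                            n_boot = config$metrics$n_boot_nri,
                            seed = derive_seed(config$seed, 32L))
    dc <- decision_curve(
      list(clinical = pred_clin, `clinical+PS` = pred_full),
      cohort, horizon, pt_grid = config$metrics$pt_grid
    )
    calib <- calibration_bins(pred_full, cohort)
    deciles <- group_cumulative_incidence(
      cohort, ps$standardized[match(cohort$id, ps$id)], horizon,
      predictions = pred_full
    )
    list(label = label, horizon = horizon,
         fit_clin = fit_clin, fit_full = fit_full,
         auc = auc, nri = nri, decision = dc,
         calibration = calib, deciles = deciles)
  }

  evals <- stage("evaluate", {
    purrr::imap(inp$cohorts, evaluate_cohort)
  })

  comparison <- stage("compare", {
    if (length(inp$cohorts) >= 2) {
      bootstrap_hr_difference(inp$cohorts, inp$membership, ps,
                              n_boot = config$metrics$n_boot_hr,
                              seed = derive_seed(config$seed, 33L))
    } else NULL
  })

  metrics <- purrr::map_dfr(evals, function(ev) {
    ps_row <- tidy(ev$fit_full) %>% filter(.data$term == "ps")
    dplyr::bind_rows(
      tibble(metric = "auc", model = "clinical", cohort = ev$label,
             estimate = ev$auc$auc_a, lo95 = NA_real_, hi95 = NA_real_),
      tibble(metric = "auc", model = "clinical+PS", cohort = ev$label,
             estimate = ev$auc$auc_b, lo95 = NA_real_, hi95 = NA_real_),
      tibble(metric = "delta_auc", model = "clinical+PS", cohort = ev$label,
             estimate = ev$auc$delta_auc,
             lo95 = ev$auc$ci95[1], hi95 = ev$auc$ci95[2]),
      tibble(metric = "nri", model = "clinical+PS", cohort = ev$label,
             estimate = ev$nri$total,
             lo95 = ev$nri$ci95[1], hi95 = ev$nri$ci95[2]),
      tibble(metric = "hr_ps_per_sd", model = "clinical+PS",
             cohort = ev$label, estimate = exp(ps_row$estimate),
             lo95 = exp(ps_row$conf.low), hi95 = exp(ps_row$conf.high))
    )
  })

  hr_tables <- purrr::map_dfr(evals, function(ev) {
    dplyr::bind_rows(
      mutate(hr_table(ev$fit_clin), model = "clinical"),
      mutate(hr_table(ev$fit_full), model = "clinical+PS")
    ) %>% mutate(cohort = ev$label)
  })

  curves <- purrr::map_dfr(evals, function(ev) {
    mutate(as_tibble(ev$decision), cohort = ev$label)
  })

  outputs <- stage("write", {
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(serialize_config(config), cfg_path,
                         auto_unbox = TRUE, digits = NA)
    run_hash <- unname(tools::md5sum(cfg_path))
    write_with_hash <- function(df, name) {
      p <- file.path(out_dir, name)
      readr::write_lines(paste0("# run: ", run_hash), p)
      readr::write_csv(df, p, append = TRUE, col_names = TRUE)
      p
    }
    paths <- c(
      cfg_path,
      write_with_hash(metrics, "metrics.csv"),
      write_with_hash(hr_tables, "hr_tables.csv"),
      write_with_hash(curves, "decision_curves.csv"),
      if (!is.null(comparison))
        write_with_hash(as_tibble(comparison), "cohort_comparison.csv"),
      write_ps_csv(ps, file.path(out_dir, "polygenic_score.csv"))
    )
    manifest <- list(
      package_version = as.character(utils::packageVersion("pgsrisk")),
      seed = config$seed,
      config_hash = run_hash,
      n_variants_selected = score$n_selected,
      outputs = lapply(setNames(nm = basename(paths)), function(nm) {
        list(md5 = unname(tools::md5sum(file.path(out_dir, nm))))
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  })

  invisible(list(
    config = config, ps = ps, harm_report = score$harm_report,
    evals = evals, metrics = metrics, hr_tables = hr_tables,
    decision_curves = curves, comparison = comparison,
    manifest = outputs
  ))
}

# Canonical (JSON-serialisable) form of a run_config, used for hashing.
serialize_config <- function(config) {
  list(
    simulation = config$simulation,
    inputs = config$inputs,
    horizons = as.list(config$horizons),
    metrics = config$metrics,
    ps_method = config$ps_method,
    seed = config$seed
  )
}
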