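# End-to-end orchestration: simulate (or read) a bundle, select the cohort,
# compute treatment patterns, fit weights with balance diagnostics, estimate
# effects with bootstrap inference, and render report tables and figures.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param n_patients Patients to simulate (ignored when `bundle_dir` given).
#' @param seed Master seed; stage substreams are derived from it and recorded
#'   in every output artifact.
#' @param B Bootstrap replications.
#' @param subcohort `"overall"` or `"recently_diagnosed"` (propensity model
#'   refit within the subcohort).
#' @param discount Also run the branded-discount cost sensitivity scenario.
#' @param refit_ps Re-estimate weights in each bootstrap replicate.
#' @param count_terminal_gap Terminal-gap mode for persistence.
#' @param accrual_start First allowed index date.
#' @param bundle_dir Optional directory with an existing claims bundle.
#' @param sim Extra overrides passed to [claims_sim_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, n_patients = 1000, seed = 1, B = 499,
                       subcohort = c("overall", "recently_diagnosed"),
                       discount = TRUE, refit_ps = TRUE,
                       count_terminal_gap = TRUE,
                       accrual_start = as.Date("2009-09-01"),
                       bundle_dir = NULL, sim = list()) {
  structure(list(out_dir = out_dir, n_patients = n_patients, seed = seed,
                 B = B, subcohort = match.arg(subcohort), discount = discount,
                 refit_ps = refit_ps, count_terminal_gap = count_terminal_gap,
                 accrual_start = as.Date(accrual_start),
                 bundle_dir = bundle_dir, sim = sim),
            class = "run_config")
}

#' Read a pipeline run configuration from a YAML or JSON file
#'
#' The file's top-level keys are the arguments of [run_config()]; the `sim`
#' key holds generator overrides for [claims_sim_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(fields), names(formals(run_config)))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown run-config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "claimsce_config_error")
  }
  do.call(run_config, fields)
}

write_artifact <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the complete comparative-effectiveness pipeline
#'
#' Stages: bundle acquisition (synthetic generation or reading), index-event
#' detection and inclusion criteria with an attrition table, subcohort
#' assignment, baseline covariates, propensity weights with unweighted and
#' weighted balance tables, weighted treatment-pattern comparison, and the
#' bootstrap outcome suite. All artifacts are written to the configured
#' output directory together with a manifest recording the seed and
#' configuration; a rerun with the same configuration reproduces every
#' numeric output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory artifacts.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$bundle_dir)) {
    bundle <- read_bundle(config$bundle_dir)
    truth <- NULL
  } else {
    sim_cfg <- do.call(claims_sim_config,
                       c(list(n_patients = config$n_patients,
                              seed = config$seed), config$sim))
    gb <- generate_bundle(sim_cfg)
    bundle <- gb$bundle
    truth <- gb$truth
    write_artifact(truth, config$out_dir, "ground_truth.csv")
  }

  events <- find_index_events(bundle, config$accrual_start)
  decisions <- apply_inclusion(bundle, events)
  decisions <- assign_subcohorts(decisions, bundle$patients)
  attrition <- tibble::tibble(
    stage = c("patients", "with_index_event",
              paste0("fail_", c("schizophrenia_dx", "age", "pre_enrollment",
                                "post_enrollment")),
              "included", "included_pp1m", "included_oaa",
              "included_recently_diagnosed"),
    n = c(nrow(bundle$patients), nrow(decisions),
          sum(!decisions$crit_b), sum(decisions$crit_b & !decisions$crit_c),
          sum(decisions$crit_b & decisions$crit_c & !decisions$crit_d),
          sum(decisions$crit_b & decisions$crit_c & decisions$crit_d &
                !decisions$crit_e),
          sum(decisions$included),
          sum(decisions$included & decisions$cohort == "PP1M"),
          sum(decisions$included & decisions$cohort == "OAA"),
          sum(decisions$included & decisions$recently_diagnosed)))
  write_artifact(attrition, config$out_dir, "attrition.csv")
  write_artifact(decisions, config$out_dir, "inclusion.csv")

  cohort <- decisions[decisions$included, ]
  if (config$subcohort == "recently_diagnosed") {
    cohort <- cohort[cohort$recently_diagnosed, ]
  }
  if (nrow(cohort) < 2 || length(unique(cohort$cohort)) < 2) {
    rlang::abort("cohort stage: fewer than two patients or a single arm after selection",
                 class = "claimsce_pipeline_error")
  }
  treated <- cohort$cohort == "PP1M"

  covs <- build_baseline_covariates(bundle, cohort)
  fit <- fit_propensity(covs, treated)
  weights <- compute_weights(fit, treated)
  write_artifact(tibble::tibble(patient_id = cohort$patient_id,
                                treated = treated, ps = fit$ps,
                                raw_weight = weights$raw_weight,
                                weight = weights$weight,
                                seed = config$seed),
                 config$out_dir, "weights.csv")
  bal_pre <- balance_table(covs, treated)
  bal_post <- balance_table(covs, treated, weights$weight)
  write_artifact(bal_pre, config$out_dir, "balance_unweighted.csv")
  write_artifact(bal_post, config$out_dir, "balance_weighted.csv")

  patterns <- exposure_summary(bundle, cohort,
                               count_terminal_gap = config$count_terminal_gap)
  write_artifact(patterns, config$out_dir, "patterns.csv")
  pattern_summary <- summarize_patterns(patterns, treated, weights$weight)
  write_artifact(pattern_summary, config$out_dir, "pattern_summary.csv")

  costs <- monthly_costs(bundle, cohort)
  util <- utilization_records(bundle, cohort)
  discount_costs <- if (config$discount) {
    monthly_costs(bundle, cohort, discount = TRUE)
  }
  effects <- run_outcome_suite(costs, util, covs, treated,
                               discount_costs = discount_costs,
                               B = config$B, seed = config$seed + 100,
                               refit_ps = config$refit_ps)
  write_artifact(effects, config$out_dir, "effects.csv")

  manifest <- list(
    package = "claimsce",
    version = as.character(utils::packageVersion("claimsce")),
    seed = config$seed, B = config$B, subcohort = config$subcohort,
    n_patients = nrow(bundle$patients), n_included = nrow(cohort),
    n_treated = sum(treated),
    weighted_n = sum(weights$weight),
    timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  report <- render_report(effects, config$out_dir)

  invisible(list(bundle = bundle, truth = truth, decisions = decisions,
                 cohort = cohort, covariates = covs, fit = fit,
                 weights = weights, balance_unweighted = bal_pre,
                 balance_weighted = bal_post, patterns = patterns,
                 pattern_summary = pattern_summary, effects = effects,
                 attrition = attrition, report = report))
}

#' Render report tables and forest-style figures
#'
#' Writes a per-category effect report (estimate, confidence interval,
#' p-value) and deterministic forest-style figures for the cost differences
#' and the rate ratios.
#'
#' @param effects Effect table from [run_outcome_suite()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(effects, dir) {
  if (is.null(effects)) {
    rlang::abort("missing artifact: effects", class = "claimsce_pipeline_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  report <- effects[c("estimand", "category", "scenario", "estimate",
                      "ci_low", "ci_high", "p_value", "B", "seed")]
  paths <- c(paths, write_artifact(report, dir, "effects_report.csv"))
  if (nrow(effects) == 0) {
    rlang::warn("empty effects table; header-only report written")
    return(invisible(paths))
  }
  plot_one <- function(sub, xlab, file, ref, log_x = FALSE) {
    if (nrow(sub) == 0) return(NULL)
    sub <- sub[!is.na(sub$estimate), ]
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$estimate,
                                           y = .data$category)) +
      ggplot2::geom_vline(xintercept = ref, linetype = 2, colour = "grey50") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                           xmax = .data$ci_high),
                              height = 0.2) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(x = xlab, y = NULL) +
      ggplot2::theme_minimal()
    if (log_x) p <- p + ggplot2::scale_x_log10()
    ggplot2::ggsave(file.path(dir, file), p, width = 7, height = 5, dpi = 150)
    file.path(dir, file)
  }
  paths <- c(paths,
             plot_one(effects[effects$estimand == "MMCD", ],
                      "Mean monthly cost difference (2015 USD)",
                      "mmcd_forest.png", ref = 0),
             plot_one(effects[effects$estimand == "RR", ],
                      "Rate ratio (per person-year)",
                      "rr_forest.png", ref = 1, log_x = TRUE))
  invisible(paths)
}
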