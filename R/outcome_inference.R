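# Cost standardization, monthly cost and utilization records, weighted
# effect estimators (mean monthly cost difference; Poisson rate ratio) and
# nonparametric bootstrap inference.

cost_categories <- function() {
  c("inpatient", "outpatient", "emergency_room", "long_term_care",
    "mhi_admission", "mhi_1day", "home_care", "other_medical")
}

los_categories <- function() c("inpatient", "long_term_care", "mhi_admission")

#' Standardize paid amounts to a reference year
#'
#' Multiplies each amount by the ratio of the reference-year medical-care CPI
#' to the service-year index.
#'
#' @param amount Numeric paid amounts.
#' @param service_year Integer service years (recycled against `amount`).
#' @param cpi Named index vector from [cpi_medical()].
#' @param target_year Reference year (default 2015).
#' @return Adjusted amounts.
#' @export
standardize_costs <- function(amount, service_year, cpi = cpi_medical(),
                              target_year = 2015) {
  if (length(amount) == 0) return(numeric())
  years <- unique(c(service_year, target_year))
  missing <- setdiff(as.character(years), names(cpi))
  if (length(missing) > 0) {
    rlang::abort(paste0("CPI table missing year(s): ", paste(missing, collapse = ", ")),
                 class = "claimsce_config_error")
  }
  unname(amount * cpi[[as.character(target_year)]] / cpi[as.character(service_year)])
}

#' Apply the branded-pharmacy discount
#'
#' Multiplies branded amounts by `1 - rate`; generic amounts are unchanged.
#' Used by the discount sensitivity scenario.
#'
#' @param amount Numeric paid amounts.
#' @param branded Logical branded flags.
#' @param rate Discount rate in `[0, 1)`; default 0.231, the mandatory
#'   minimum Medicaid discount for branded pharmaceuticals.
#' @return Adjusted amounts.
#' @export
apply_brand_discount <- function(amount, branded, rate = 0.231) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    rlang::abort("discount rate must be in [0, 1)", class = "claimsce_config_error")
  }
  ifelse(branded, amount * (1 - rate), amount)
}

#' Monthly costs per patient and category
#'
#' Sums standardized paid amounts over the fixed 365-day observation window
#' and divides by 12. Categories: the medical service categories (the `other`
#' service category is reported as `other_medical`), `pharmacy`,
#' `total_medical` (sum of medical categories) and `total`
#' (`total_medical + pharmacy`).
#'
#' @param bundle A `claims_bundle`.
#' @param events Included index events.
#' @param cpi CPI table.
#' @param target_year Cost reference year.
#' @param discount Apply the branded-pharmacy discount (sensitivity scenario).
#' @param discount_rate Discount rate when `discount` is `TRUE`.
#' @return A tibble, one row per event, `patient_id` plus one column per
#'   category of monthly cost in reference-year dollars.
#' @export
monthly_costs <- function(bundle, events, cpi = cpi_medical(), target_year = 2015,
                          discount = FALSE, discount_rate = 0.231) {
  out <- tibble::tibble(patient_id = events$patient_id)
  for (cat in c(cost_categories(), "pharmacy")) out[[cat]] <- 0
  idx <- stats::setNames(seq_len(nrow(events)), events$patient_id)
  index_of <- stats::setNames(events$index_date, events$patient_id)

  md <- bundle$medical[bundle$medical$patient_id %in% events$patient_id, ]
  if (nrow(md) > 0) {
    rel <- as.integer(md$start_date - index_of[md$patient_id])
    keep <- rel >= 0L & rel <= 364L
    md <- md[keep, ]
    if (nrow(md) > 0) {
      amt <- standardize_costs(md$paid_amount, md$service_year, cpi, target_year)
      cat <- ifelse(md$service_category == "other", "other_medical",
                    md$service_category)
      for (k in unique(cat)) {
        sums <- tapply(amt[cat == k], md$patient_id[cat == k], sum)
        out[[k]][idx[names(sums)]] <- unname(sums)
      }
    }
  }
  ph <- bundle$pharmacy[bundle$pharmacy$patient_id %in% events$patient_id, ]
  if (nrow(ph) > 0) {
    rel <- as.integer(ph$dispense_date - index_of[ph$patient_id])
    ph <- ph[rel >= 0L & rel <= 364L, ]
    if (nrow(ph) > 0) {
      amt <- standardize_costs(ph$paid_amount, ph$service_year, cpi, target_year)
      if (discount) amt <- apply_brand_discount(amt, ph$branded, discount_rate)
      sums <- tapply(amt, ph$patient_id, sum)
      out$pharmacy[idx[names(sums)]] <- unname(sums)
    }
  }
  out$total_medical <- rowSums(out[cost_categories()])
  out$total <- out$total_medical + out$pharmacy
  for (k in setdiff(names(out), "patient_id")) out[[k]] <- out[[k]] / 12
  out
}

#' Utilization counts and days per patient and category
#'
#' Event counts per medical service category over the observation window, and
#' lengths of stay (days) for inpatient, long-term-care and multi-day
#' mental-health-institute admissions. Person-time is fixed at one
#' person-year per patient (365-day window).
#'
#' @param bundle A `claims_bundle`.
#' @param events Included index events.
#' @return A tibble, one row per event: `patient_id`, `ev_<category>` counts,
#'   `days_<category>` day totals and `person_years`.
#' @export
utilization_records <- function(bundle, events) {
  out <- tibble::tibble(patient_id = events$patient_id)
  for (cat in service_category_levels()) out[[paste0("ev_", cat)]] <- 0L
  for (cat in los_categories()) out[[paste0("days_", cat)]] <- 0L
  idx <- stats::setNames(seq_len(nrow(events)), events$patient_id)
  index_of <- stats::setNames(events$index_date, events$patient_id)

  md <- bundle$medical[bundle$medical$patient_id %in% events$patient_id, ]
  if (nrow(md) > 0) {
    rel <- as.integer(md$start_date - index_of[md$patient_id])
    md <- md[rel >= 0L & rel <= 364L, ]
  }
  if (nrow(md) > 0) {
    for (k in unique(md$service_category)) {
      sub <- md[md$service_category == k, ]
      cnt <- tapply(rep(1L, nrow(sub)), sub$patient_id, sum)
      out[[paste0("ev_", k)]][idx[names(cnt)]] <- unname(as.integer(cnt))
      if (k %in% los_categories()) {
        los <- as.integer(sub$end_date - sub$start_date + 1L)
        d <- tapply(los, sub$patient_id, sum)
        out[[paste0("days_", k)]][idx[names(d)]] <- unname(as.integer(d))
      }
    }
  }
  out$person_years <- 1
  out
}

#' Weighted mean monthly cost difference
#'
#' Treatment coefficient of a weighted least-squares regression of monthly
#' cost on an intercept and the treatment indicator; identical to the
#' difference in weighted arm means.
#'
#' @param y Monthly costs.
#' @param treated Logical treatment indicator.
#' @param weights Normalized weights.
#' @return The cost difference (treated minus comparator).
#' @export
estimate_mmcd <- function(y, treated, weights = rep(1, length(y))) {
  if (sum(weights[treated]) <= 0 || sum(weights[!treated]) <= 0) {
    rlang::abort("zero weight sum in an arm", class = "claimsce_estimation_error")
  }
  fit <- stats::lm.wfit(cbind(1, as.numeric(treated)), y, weights)
  unname(fit$coefficients[2])
}

#' Weighted Poisson rate ratio
#'
#' Exponentiated treatment coefficient of a weighted Poisson regression with
#' log link and a log person-time offset; with equal person-time it equals
#' the ratio of weighted event rates.
#'
#' @param y Event (or day) counts.
#' @param treated Logical treatment indicator.
#' @param weights Normalized weights.
#' @param person_years Person-time per patient (default 1).
#' @return The rate ratio (treated over comparator).
#' @export
estimate_rr <- function(y, treated, weights = rep(1, length(y)), person_years = 1) {
  person_years <- rep_len(person_years, length(y))
  if (sum(weights[!treated] * y[!treated]) <= 0) {
    rlang::abort("comparator weighted event total is zero; rate ratio undefined",
                 class = "claimsce_estimation_error")
  }
  if (sum(weights[treated] * y[treated]) <= 0) return(0)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, as.numeric(treated)), y, weights = weights,
                   offset = log(person_years), family = stats::poisson(),
                   control = stats::glm.control(epsilon = 1e-12)))
  unname(exp(fit$coefficients[2]))
}

# Stratified bootstrap: resample patients with replacement within each arm,
# preserving arm sizes; returns a B x k matrix of statistic values. Failed
# replicates are dropped; more than `max_fail` failures is an error.
boot_replicates <- function(statistic, treated, B, seed, max_fail = 0.05) {
  set.seed(seed)
  i_t <- which(treated); i_c <- which(!treated)
  reps <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- c(sample(i_t, length(i_t), replace = TRUE),
             sample(i_c, length(i_c), replace = TRUE))
    reps[[b]] <- tryCatch(statistic(idx), error = function(e) NULL)
    if (is.null(reps[[b]])) failed <- failed + 1L
  }
  if (failed > max_fail * B) {
    rlang::abort(sprintf("bootstrap: %d of %d replicates failed", failed, B),
                 class = "claimsce_inference_error")
  }
  do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
}

# Percentile CI and percentile-inversion two-sided p-value against the null
# (0 for cost differences, log 0 for rate ratios, computed on the log scale).
boot_summary <- function(point, draws, estimand) {
  if (estimand == "RR") {
    ldraws <- log(pmax(draws, .Machine$double.xmin))
    p <- 2 * min(sum(ldraws <= 0), sum(ldraws >= 0)) / length(draws)
  } else {
    p <- 2 * min(sum(draws <= 0), sum(draws >= 0)) / length(draws)
  }
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  list(ci_low = ci[1], ci_high = ci[2], p_value = min(p, 1))
}

#' Bootstrap inference for a single weighted effect estimate
#'
#' Resamples patients with replacement within each treatment cohort
#' (preserving cohort sizes); per replicate the propensity model and weights
#' are re-estimated by default, then the estimand recomputed. The 95%
#' confidence interval is the 2.5/97.5 percentile interval of the replicates;
#' the two-sided p-value inverts the percentile position of the null (zero
#' cost difference; unit rate ratio, assessed on the log scale).
#'
#' @param y Outcome vector (monthly costs, or counts for rate ratios).
#' @param treated Logical treatment indicator.
#' @param covariates Baseline covariates (for propensity refitting), or
#'   `NULL` with fixed `weights`.
#' @param estimand `"MMCD"` or `"RR"`.
#' @param B Bootstrap replications (default 499).
#' @param seed Seed for the resampling stream.
#' @param refit_ps Re-estimate the propensity model per replicate (default
#'   `TRUE` when covariates are supplied).
#' @param weights Full-sample weights (required when not refitting).
#' @param ps_vars Covariate columns for the propensity design.
#' @return A one-row tibble: estimand, point estimate, CI bounds, p-value, B
#'   and seed.
#' @export
bootstrap_inference <- function(y, treated, covariates = NULL,
                                estimand = c("MMCD", "RR"), B = 499, seed = 1,
                                refit_ps = !is.null(covariates), weights = NULL,
                                ps_vars = NULL) {
  estimand <- match.arg(estimand)
  est_fun <- if (estimand == "MMCD") estimate_mmcd else estimate_rr
  design <- if (is.matrix(covariates)) covariates
  else if (!is.null(covariates)) build_ps_design(covariates, ps_vars)
  if (is.null(weights)) {
    if (is.null(design)) rlang::abort("need covariates or weights")
    weights <- compute_weights(fit_propensity(design, treated), treated)$weight
  }
  point <- est_fun(y, treated, weights)
  statistic <- function(idx) {
    w <- if (refit_ps) {
      suppressWarnings(
        compute_weights(fit_propensity(design[idx, , drop = FALSE], treated[idx]),
                        treated[idx])$weight)
    } else {
      weights[idx] / mean(weights[idx])
    }
    est_fun(y[idx], treated[idx], w)
  }
  draws <- boot_replicates(statistic, treated, B, seed)[, 1]
  s <- boot_summary(point, draws, estimand)
  tibble::tibble(estimand = estimand, estimate = point,
                 ci_low = s$ci_low, ci_high = s$ci_high, p_value = s$p_value,
                 B = length(draws), seed = seed)
}

#' Full weighted outcome suite with joint bootstrap
#'
#' Computes every cost-category mean monthly cost difference and every
#' utilization-category rate ratio (event and day measures), for the main
#' scenario and, when discounted costs are supplied, the branded-discount
#' sensitivity scenario. All estimands share the same bootstrap replicates:
#' each replicate resamples patients within cohort, re-estimates the
#' propensity model and weights (by default), and recomputes every estimand.
#' No multiplicity adjustment is applied.
#'
#' @param costs Monthly cost table from [monthly_costs()] (main scenario).
#' @param util Utilization table from [utilization_records()].
#' @param covariates Baseline covariates for the propensity model.
#' @param treated Logical treatment indicator aligned to rows.
#' @param discount_costs Optional cost table for the sensitivity scenario.
#' @param B,seed Bootstrap replications and seed.
#' @param refit_ps Re-estimate weights per replicate (default `TRUE`).
#' @param ps_vars Covariate columns for the propensity design.
#' @return A tibble of effect estimates: `estimand`, `category`, `scenario`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `B`, `seed`.
#' @export
run_outcome_suite <- function(costs, util, covariates, treated,
                              discount_costs = NULL, B = 499, seed = 1,
                              refit_ps = TRUE, ps_vars = NULL) {
  design <- build_ps_design(covariates, ps_vars)
  full_w <- compute_weights(fit_propensity(design, treated), treated)$weight

  cost_cols <- setdiff(names(costs), "patient_id")
  util_cols <- setdiff(names(util), c("patient_id", "person_years"))
  spec <- list()
  for (k in cost_cols) {
    spec[[paste0("MMCD.", k, ".main")]] <-
      list(estimand = "MMCD", category = k, scenario = "main", y = costs[[k]])
  }
  if (!is.null(discount_costs)) {
    for (k in c("pharmacy", "total")) {
      spec[[paste0("MMCD.", k, ".discount")]] <-
        list(estimand = "MMCD", category = k, scenario = "discount",
             y = discount_costs[[k]])
    }
  }
  for (k in util_cols) {
    measure <- if (startsWith(k, "days_")) "days" else "events"
    cat <- sub("^(ev|days)_", "", k)
    spec[[paste0("RR.", k, ".main")]] <-
      list(estimand = "RR", category = paste0(cat, "_", measure),
           scenario = "main", y = util[[k]])
  }

  eval_all <- function(idx, w) {
    vapply(spec, function(s) {
      tryCatch({
        if (s$estimand == "MMCD") estimate_mmcd(s$y[idx], treated[idx], w)
        else estimate_rr(s$y[idx], treated[idx], w, util$person_years[idx])
      }, claimsce_estimation_error = function(e) NA_real_)
    }, numeric(1))
  }
  points <- eval_all(seq_along(treated), full_w)
  statistic <- function(idx) {
    w <- if (refit_ps) {
      suppressWarnings(
        compute_weights(fit_propensity(design[idx, , drop = FALSE], treated[idx]),
                        treated[idx])$weight)
    } else {
      full_w[idx] / mean(full_w[idx])
    }
    eval_all(idx, w)
  }
  draws <- boot_replicates(statistic, treated, B, seed)

  rows <- lapply(names(spec), function(nm) {
    d <- draws[, nm]
    d_ok <- d[!is.na(d)]
    if (is.na(points[[nm]]) || length(d_ok) == 0) {
      return(tibble::tibble(estimand = spec[[nm]]$estimand,
                            category = spec[[nm]]$category,
                            scenario = spec[[nm]]$scenario,
                            estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            B = 0L, seed = seed))
    }
    s <- boot_summary(points[[nm]], d_ok, spec[[nm]]$estimand)
    tibble::tibble(estimand = spec[[nm]]$estimand, category = spec[[nm]]$category,
                   scenario = spec[[nm]]$scenario, estimate = points[[nm]],
                   ci_low = s$ci_low, ci_high = s$ci_high, p_value = s$p_value,
                   B = length(d_ok), seed = seed)
  })
  dplyr::bind_rows(rows)
}
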