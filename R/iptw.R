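# Propensity scores, normalized inverse-probability-of-treatment weights, and
# standardized-difference balance diagnostics.

#' Default propensity-model covariates
#'
#' Column names of the baseline covariate record entering the propensity
#' model: demographics, insurance eligibility, index year/quarter, comorbidity
#' index and flags, medication-history summaries, baseline adherence category,
#' baseline utilization counts and baseline monthly costs. The total-cost
#' column is excluded (it is the sum of the pharmacy and medical columns).
#'
#' @return Character vector of covariate names.
#' @export
default_ps_vars <- function() {
  c("age_at_index", "sex", "race", "state", "region", "capitated",
    "dual_coverage", "index_year", "index_quarter", "quan_cci",
    "n_unique_mh_dx", "n_unique_psych_agents", "ap_typical_oral",
    "ap_atypical_oral", "ap_typical_lai", "ap_atypical_lai",
    "baseline_pdc_cat", "ap_polypharmacy", "use_anxiolytic",
    "use_antidepressant", "use_mood_stabilizer", "cm_cardiovascular",
    "cm_diabetes", "cm_obesity", "cm_drug_abuse", "cm_hepatitis_c",
    "cm_hiv_aids", "n_mhi_admissions", "n_mhi_1day",
    "baseline_monthly_pharmacy", "baseline_monthly_medical")
}

#' Build a propensity design matrix
#'
#' Expands a covariate data frame into a numeric model matrix with intercept.
#' Character columns and the index year/quarter become factors; covariate
#' columns (and factor levels) that are constant in the data are dropped as
#' empty categories.
#'
#' @param covariates Data frame of baseline covariates.
#' @param vars Covariate columns to use; defaults to the intersection of
#'   [default_ps_vars()] with the available columns.
#' @return Numeric matrix with an `(Intercept)` column.
#' @export
build_ps_design <- function(covariates, vars = NULL) {
  if (is.null(vars)) vars <- intersect(default_ps_vars(), names(covariates))
  if (length(vars) == 0) vars <- setdiff(names(covariates), "patient_id")
  df <- as.data.frame(covariates[vars])
  for (v in names(df)) {
    if (is.character(df[[v]]) || v %in% c("index_year", "index_quarter")) {
      df[[v]] <- factor(df[[v]])
    }
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  }
  x <- stats::model.matrix(~ ., data = df)
  constant <- apply(x, 2, function(col) all(col == col[1]))
  constant["(Intercept)"] <- FALSE
  x[, !constant, drop = FALSE]
}

#' Fit the propensity-score logistic model
#'
#' Maximum-likelihood logistic regression of treatment on baseline covariates
#' (iteratively reweighted least squares). Fitted probabilities are clipped
#' away from 0 and 1.
#'
#' @param covariates Data frame of baseline covariates, or a ready numeric
#'   design matrix.
#' @param treated Logical treatment indicator.
#' @param vars Covariate columns (see [build_ps_design()]).
#' @param epsilon Convergence tolerance passed to the IRLS control.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param clip Probability clipping bound (default `1e-6`).
#' @return An object of class `propensity_fit`: coefficients, clipped
#'   per-patient scores `ps`, convergence information and the design column
#'   names.
#' @export
fit_propensity <- function(covariates, treated, vars = NULL,
                           epsilon = 1e-8, max_iter = 100, clip = 1e-6) {
  treated <- as.logical(treated)
  if (sum(treated) < 1 || sum(!treated) < 1) {
    rlang::abort("need at least one patient per arm", class = "claimsce_estimation_error")
  }
  x <- if (is.matrix(covariates)) covariates else build_ps_design(covariates, vars)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    rlang::abort(paste0("rank-deficient propensity design; collinear column(s): ",
                        paste(dropped, collapse = ", ")),
                 class = "claimsce_design_error")
  }
  fit <- stats::glm.fit(x, as.numeric(treated), family = stats::binomial(),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = max_iter))
  if (!fit$converged) {
    rlang::abort(paste0("propensity model did not converge in ", fit$iter,
                        " iterations"),
                 class = "claimsce_estimation_error")
  }
  ps <- pmin(pmax(fit$fitted.values, clip), 1 - clip)
  structure(list(coefficients = fit$coefficients, ps = unname(ps),
                 converged = fit$converged, iterations = fit$iter,
                 design_columns = colnames(x), clip = clip),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> ", length(x$ps), " patients, ",
      length(x$coefficients), " coefficients, converged in ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Inverse-probability-of-treatment weights
#'
#' Raw weights are `1/PS` for treated and `1/(1-PS)` for comparator patients;
#' each weight is then normalized by the mean raw weight over all patients,
#' so normalized weights sum to the total patient count.
#'
#' @param fit A `propensity_fit`, or a numeric vector of propensity scores.
#' @param treated Logical treatment indicator.
#' @return A tibble with columns `raw_weight` and `weight` (normalized).
#' @export
compute_weights <- function(fit, treated) {
  ps <- if (inherits(fit, "propensity_fit")) fit$ps else as.numeric(fit)
  clip <- if (inherits(fit, "propensity_fit")) fit$clip else 1e-6
  stopifnot(length(ps) == length(treated))
  if (any(ps <= clip | ps >= 1 - clip)) {
    rlang::warn("propensity scores at the clipping boundary produce extreme weights")
  }
  raw <- ifelse(treated, 1 / ps, 1 / (1 - ps))
  tibble::tibble(raw_weight = raw, weight = raw / mean(raw))
}

#' Standardized difference for a binary covariate
#'
#' `100 * (p1 - p2) / sqrt(p * (1 - p))` with `p = (p1 + p2) / 2`. Returned
#' signed; balance tables report the absolute value. Degenerate pooled
#' proportions (0 or 1) return 0 with a warning.
#'
#' @param p1,p2 Proportions in the two cohorts.
#' @return Standardized difference in percent.
#' @export
std_diff_binary <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  if (pbar <= 0 || pbar >= 1) {
    if (p1 != p2) rlang::warn("degenerate pooled proportion; standardized difference undefined, returning 0")
    return(0)
  }
  100 * (p1 - p2) / sqrt(pbar * (1 - pbar))
}

#' Standardized difference for a continuous covariate
#'
#' `100 * |mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` (pooled standard
#' deviation as the root of the average squared standard deviations).
#'
#' @param mean1,sd1,mean2,sd2 Cohort means and standard deviations.
#' @return Standardized difference in percent.
#' @export
std_diff_continuous <- function(mean1, sd1, mean2, sd2) {
  if (mean1 == mean2) return(0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    rlang::abort("both standard deviations are zero with unequal means",
                 class = "claimsce_estimation_error")
  }
  100 * abs(mean1 - mean2) / pooled
}

#' Covariate balance table
#'
#' One row per covariate (multi-level categoricals expanded to one row per
#' level, compared as binaries). Summaries use the frequency-weight
#' convention (denominator = sum of weights); the balance flag applies the
#' 10% threshold to the absolute standardized difference.
#'
#' @param covariates Data frame of covariates (columns `patient_id` ignored).
#' @param treated Logical treatment indicator.
#' @param weights Optional weights (default unweighted).
#' @param threshold Balance threshold in percent (default 10).
#' @return A tibble with cohort summaries, `std_diff` (absolute, percent) and
#'   a `balanced` flag.
#' @export
balance_table <- function(covariates, treated, weights = NULL, threshold = 10) {
  if (is.null(weights)) weights <- rep(1, length(treated))
  if (sum(weights[treated]) == 0 || sum(weights[!treated]) == 0) {
    rlang::abort("empty arm after weighting", class = "claimsce_estimation_error")
  }
  vars <- setdiff(names(covariates), "patient_id")
  rows <- list()
  for (v in vars) {
    x <- covariates[[v]]
    if (is.character(x) || is.factor(x)) {
      for (lev in sort(unique(as.character(x)))) {
        rows[[paste0(v, ":", lev)]] <- balance_row(paste0(v, ":", lev),
                                                   x == lev, treated, weights)
      }
    } else if (is.logical(x)) {
      rows[[v]] <- balance_row(v, x, treated, weights)
    } else {
      a <- weighted_mean_sd(x[treated], weights[treated])
      b <- weighted_mean_sd(x[!treated], weights[!treated])
      rows[[v]] <- tibble::tibble(
        covariate = v, type = "continuous",
        treated_value = a[["mean"]], comparator_value = b[["mean"]],
        treated_sd = a[["sd"]], comparator_sd = b[["sd"]],
        std_diff = std_diff_continuous(a[["mean"]], a[["sd"]], b[["mean"]], b[["sd"]]))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$balanced <- abs(out$std_diff) <= threshold
  out
}

balance_row <- function(name, flag, treated, weights) {
  p1 <- sum(weights[treated] * flag[treated]) / sum(weights[treated])
  p2 <- sum(weights[!treated] * flag[!treated]) / sum(weights[!treated])
  tibble::tibble(covariate = name, type = "binary",
                 treated_value = p1, comparator_value = p2,
                 treated_sd = NA_real_, comparator_sd = NA_real_,
                 std_diff = abs(std_diff_binary(p1, p2)))
}
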