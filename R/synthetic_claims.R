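# Synthetic Medicaid-like claims with known ground truth: confounded
# treatment assignment through observed covariates, renewal-process pharmacy
# fills with a controllable PDC distribution, gamma-with-zero-mass cost
# outcomes carrying a known additive monthly treatment effect, and Poisson
# utilization counts carrying a known rate ratio.

#' Configuration for the synthetic claims generator
#'
#' Defaults define the generator's study conditions: a Medicaid-like adult
#' schizophrenia population, treatment assignment confounded by observed
#' covariates via a logistic model, a geometric refill-gap model whose mean
#' extra gap controls the implied PDC (expected long-run PDC is
#' `days_supply / (days_supply + gap_mean)` absent discontinuation), an
#' additive true monthly medical-cost effect `delta_true` and a
#' multiplicative true utilization rate ratio `rr_true`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param seed Master seed; stage seeds are derived from it.
#' @param ... Overrides for any default component (see the returned list).
#' @return A list of class `claims_sim_config`.
#' @export
claims_sim_config <- function(n_patients = 2000, seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    accrual_start = as.Date("2010-01-01"), accrual_end = as.Date("2013-12-31"),
    # covariate model
    age_mean = 40, age_sd = 13, age_min = 18, age_max = 64,
    p_female = 0.5,
    race_probs = c(white = 0.50, black = 0.35, hispanic = 0.01,
                   other = 0.07, unknown = 0.07),
    state_probs = c(IA = 0.07, KS = 0.09, MS = 0.11, MO = 0.48, NJ = 0.25),
    region_probs = c(urban = 0.55, suburban = 0.27, rural = 0.18),
    p_capitated = 0.45, p_dual = 0.30,
    como_prev = c(cardiovascular = 0.15, diabetes = 0.20, obesity = 0.10,
                  drug_abuse = 0.20, hepatitis_c = 0.04, hiv_aids = 0.015),
    extra_cci_prev = c(copd = 0.10, renal = 0.04),
    p_prior_ap = 0.65, p_baseline_support = 0.60,
    mhi_rate = 0.6, mhi1_rate = 1.5,
    # treatment model: coefficients on treatment_design() columns
    beta = c(intercept = -1.1, age10 = -0.25, female = -0.5, prior_ap = 0.9,
             mhi = 0.25, drug_abuse = 0.3, como = -0.2),
    # fill model
    fill = list(days_supply = 30L, gap_mean = c(pp1m = 10, oaa = 16),
                gap_log_sd = 0.6, gap_dist = "geometric",
                p_discontinue = c(pp1m = 0.05, oaa = 0.07),
                first_gap_max = 60L),
    p_no_second_fill = 0.02, p_pp1m_medical = 0.20,
    p_conc_ap = 0.35, p_conc_support = 0.60,
    # outcome model
    cost_base = 1800, cost_age = 8, cost_prior_ap = 300, cost_mhi = 250,
    cost_drug_abuse = 200, cost_shape = 1.5, p_zero_cost = 0.08,
    delta_true = -300, rr_true = 0.84,
    rate_base = c(outpatient = 12, emergency_room = 2, inpatient = 1.2,
                  long_term_care = 0.15, mhi_admission = 0.8, mhi_1day = 2.5,
                  home_care = 3, other = 1.5),
    rate_prior_ap = 0.25, rate_mhi = 0.10,
    los_mean = c(inpatient = 5, long_term_care = 20, mhi_admission = 7),
    fill_price = c(pp1m = 1100, oaa = 180, background = 40),
    baseline_cost_base = 1500, baseline_cost_shape = 1.2,
    # enrollment model
    p_baseline_gap = 0.02, p_followup_gap = 0.02, gap_length = 15L,
    p_missing_scz = 0.01
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
                 class = "claimsce_config_error")
  }
  cfg[names(over)] <- over
  validate_sim_config(structure(cfg, class = "claims_sim_config"))
}

validate_sim_config <- function(cfg) {
  ok <- function(p) all(p >= 0 & p <= 1)
  if (cfg$n_patients < 2) {
    rlang::abort("n_patients must be at least 2", class = "claimsce_config_error")
  }
  if (!ok(cfg$race_probs) || !ok(cfg$state_probs) || !ok(cfg$region_probs) ||
      !ok(cfg$como_prev) || !ok(c(cfg$p_female, cfg$p_capitated, cfg$p_dual,
                                  cfg$p_prior_ap, cfg$p_zero_cost))) {
    rlang::abort("probabilities must lie in [0, 1]", class = "claimsce_config_error")
  }
  if (cfg$fill$days_supply < 1 || any(cfg$fill$gap_mean < 0)) {
    rlang::abort("invalid fill model", class = "claimsce_config_error")
  }
  if (cfg$cost_shape <= 0 || cfg$baseline_cost_shape <= 0) {
    rlang::abort("dispersion parameters must be positive", class = "claimsce_config_error")
  }
  cfg
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate patient-level covariates
#'
#' Draws demographics, comorbidity flags, baseline-utilization latents, the
#' latent adherence propensity and an index date per patient; also returns
#' the patient and enrollment tables implied by those draws. Deterministic
#' given `(config, seed)`.
#'
#' @param config A [claims_sim_config()].
#' @param seed Seed (defaults to the config's covariate substream).
#' @param tables Also materialize the patient and enrollment tables (skipped
#'   by the patient-level simulation path, which needs only the covariates).
#' @return A list: `covariates` (one row per patient), `patients`,
#'   `enrollment` (the latter two `NULL` when `tables = FALSE`).
#' @export
generate_covariates <- function(config, seed = config$seed + 1, tables = TRUE) {
  set.seed(seed)
  n <- config$n_patients
  age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)),
                   config$age_min), config$age_max)
  covs <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    index_date = config$accrual_start +
      sample.int(as.integer(config$accrual_end - config$accrual_start) + 1L,
                 n, replace = TRUE) - 1L,
    age = age,
    female = runif(n) < config$p_female,
    race = sample_levels(n, config$race_probs),
    state = sample_levels(n, config$state_probs),
    region = sample_levels(n, config$region_probs),
    capitated = runif(n) < config$p_capitated,
    dual_coverage = runif(n) < config$p_dual,
    prior_ap = runif(n) < config$p_prior_ap,
    baseline_support = runif(n) < config$p_baseline_support,
    adherence_z = rnorm(n),
    gap_baseline = runif(n) < config$p_baseline_gap,
    gap_followup = runif(n) < config$p_followup_gap,
    no_second_fill = runif(n) < config$p_no_second_fill,
    missing_scz = runif(n) < config$p_missing_scz,
    pp1m_medical = runif(n) < config$p_pp1m_medical
  )
  for (nm in names(config$como_prev)) {
    covs[[paste0("cm_", nm)]] <- runif(n) < config$como_prev[[nm]]
  }
  for (nm in names(config$extra_cci_prev)) {
    covs[[paste0("cx_", nm)]] <- runif(n) < config$extra_cci_prev[[nm]]
  }
  covs$n_mhi_baseline <- rpois(n, config$mhi_rate * (1 + covs$prior_ap))
  covs$n_mhi1_baseline <- rpois(n, config$mhi1_rate * (1 + covs$prior_ap))

  if (!tables) {
    return(list(covariates = covs, patients = NULL, enrollment = NULL))
  }
  birth <- covs$index_date - round((covs$age + runif(n, 0.02, 0.98)) * 365.25)
  patients <- tibble::tibble(
    patient_id = covs$patient_id, birth_date = birth,
    sex = ifelse(covs$female, "female", "male"),
    race = covs$race, region = covs$region, state = covs$state
  )
  enrollment <- build_enrollment(covs, config)
  list(covariates = covs, patients = patients, enrollment = enrollment)
}

# One long span per patient, split by a hole in the baseline and/or
# follow-up year when the corresponding gap flag is set.
build_enrollment <- function(covs, config) {
  pieces <- list(
    tibble::tibble(  # segment up to (and including) any baseline hole start
      patient_id = covs$patient_id,
      start = covs$index_date - 380L,
      end = dplyr::if_else(covs$gap_baseline, covs$index_date - 151L,
                           dplyr::if_else(covs$gap_followup,
                                          covs$index_date + 99L,
                                          covs$index_date + 380L))),
    tibble::tibble(  # middle segment for patients with a baseline hole
      patient_id = covs$patient_id[covs$gap_baseline],
      start = covs$index_date[covs$gap_baseline] - 150L + config$gap_length,
      end = dplyr::if_else(covs$gap_followup[covs$gap_baseline],
                           covs$index_date[covs$gap_baseline] + 99L,
                           covs$index_date[covs$gap_baseline] + 380L)),
    tibble::tibble(  # trailing segment after a follow-up hole
      patient_id = covs$patient_id[covs$gap_followup],
      start = covs$index_date[covs$gap_followup] + 100L + config$gap_length,
      end = covs$index_date[covs$gap_followup] + 380L))
  spans <- dplyr::bind_rows(pieces)
  spans <- spans[order(match(spans$patient_id, covs$patient_id), spans$start), ]
  flags <- match(spans$patient_id, covs$patient_id)
  tibble::tibble(patient_id = spans$patient_id,
                 start_date = spans$start, end_date = spans$end,
                 capitated = covs$capitated[flags],
                 dual_coverage = covs$dual_coverage[flags])
}

treatment_design <- function(covs) {
  cbind(intercept = 1,
        age10 = (covs$age - 40) / 10,
        female = as.numeric(covs$female),
        prior_ap = as.numeric(covs$prior_ap),
        mhi = pmin(covs$n_mhi_baseline, 4),
        drug_abuse = as.numeric(covs$cm_drug_abuse),
        como = as.numeric(covs$cm_diabetes | covs$cm_cardiovascular))
}

#' Assign treatment with confounding
#'
#' Draws treatment labels from a Bernoulli whose probability is the logistic
#' transform of a linear predictor on the observed covariates, and returns
#' both the label and the true assignment probability.
#'
#' @param covs Covariate table from [generate_covariates()].
#' @param beta Named coefficient vector over the design columns (intercept,
#'   centered age decade, female, prior antipsychotic use, capped baseline
#'   admission count, drug abuse, somatic comorbidity).
#' @param seed Seed.
#' @return A tibble with `treated` (logical) and `true_ps`.
#' @export
assign_treatment <- function(covs, beta, seed) {
  x <- treatment_design(covs)
  if (length(beta) != ncol(x)) {
    rlang::abort(sprintf("beta has length %d but the design has %d columns",
                         length(beta), ncol(x)),
                 class = "claimsce_config_error")
  }
  lp <- drop(x %*% beta)
  ps <- 1 / (1 + exp(-lp))
  set.seed(seed)
  tibble::tibble(treated = runif(nrow(covs)) < ps, true_ps = ps)
}

#' Generate index-agent fills as a renewal process
#'
#' Fill days start at 0 (the index date); each fill covers `days_supply`
#' days, and the next fill follows after an extra gap drawn from the
#' configured distribution (geometric with the arm's mean, scaled by the
#' patient's adherence latent, or fixed at the mean). The first extra gap is
#' truncated so the second fill falls within 90 days of the first; after
#' each fill the patient may discontinue. Expected long-run PDC without
#' discontinuation is `days_supply / (days_supply + gap_mean)`.
#'
#' @param arm `"pp1m"` or `"oaa"`.
#' @param fill_cfg The `fill` component of a [claims_sim_config()].
#' @param adherence_z Patient adherence latent (log-scale gap multiplier).
#' @param seed Optional seed.
#' @param horizon Days of follow-up (default 365).
#' @param no_second_fill Force a single qualifying fill (for exercising the
#'   two-claims criterion).
#' @return A tibble with `day` (offsets) and `days_supply`.
#' @export
generate_fills <- function(arm, fill_cfg, adherence_z = 0, seed = NULL,
                           horizon = 365L, no_second_fill = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  s <- fill_cfg$days_supply
  mu <- fill_cfg$gap_mean[[arm]] * exp(fill_cfg$gap_log_sd * adherence_z)
  p_disc <- fill_cfg$p_discontinue[[arm]]
  draw_gap <- function() {
    if (fill_cfg$gap_dist == "fixed") round(mu) else rgeom(1, 1 / (1 + mu))
  }
  days <- 0L
  t <- 0L
  repeat {
    if (runif(1) < p_disc) break
    extra <- draw_gap()
    if (length(days) == 1L) {
      if (no_second_fill) break
      extra <- min(extra, fill_cfg$first_gap_max)
    }
    t <- t + s + as.integer(extra)
    if (t >= horizon) break
    days <- c(days, t)
  }
  tibble::tibble(day = days, days_supply = as.integer(s))
}

#' Simulate patient-level outcome values
#'
#' The fast patient-level outcome path: monthly medical cost from a gamma
#' distribution with a zero point mass, arm mean equal to the covariate terms
#' plus `delta_true` for treated patients, and per-category annual event
#' counts from a Poisson log-linear model carrying `log(rr_true)` for treated
#' patients; length-of-stay day totals for the admission categories.
#'
#' @param covs Covariate table.
#' @param treated Logical treatment labels.
#' @param config A [claims_sim_config()].
#' @param seed Seed.
#' @return A tibble with `monthly_medical_cost`, `true_mean_cost`,
#'   `ev_<category>` and `days_<category>` columns.
#' @export
simulate_outcome_values <- function(covs, treated, config, seed) {
  set.seed(seed)
  n <- nrow(covs)
  mu <- config$cost_base + config$cost_age * (covs$age - 40) +
    config$cost_prior_ap * covs$prior_ap +
    config$cost_mhi * pmin(covs$n_mhi_baseline, 4) +
    config$cost_drug_abuse * covs$cm_drug_abuse +
    config$delta_true * treated
  mu <- pmax(mu, 50)
  zero <- runif(n) < config$p_zero_cost
  gmean <- mu / (1 - config$p_zero_cost)
  cost <- ifelse(zero, 0,
                 rgamma(n, shape = config$cost_shape,
                        scale = gmean / config$cost_shape))
  out <- tibble::tibble(monthly_medical_cost = cost, true_mean_cost = mu)
  lp <- config$rate_prior_ap * covs$prior_ap +
    config$rate_mhi * pmin(covs$n_mhi_baseline, 4) +
    log(config$rr_true) * treated
  for (cat in names(config$rate_base)) {
    lam <- config$rate_base[[cat]] * exp(lp)
    out[[paste0("ev_", cat)]] <- rpois(n, lam)
  }
  for (cat in names(config$los_mean)) {
    ev <- out[[paste0("ev_", cat)]]
    extra_mean <- max(config$los_mean[[cat]] - 1, 0)
    out[[paste0("days_", cat)]] <- ev + rpois(n, extra_mean * ev) +
      (cat == "mhi_admission") * ev  # multi-day admissions span >1 day
    out[[paste0("days_", cat)]][ev == 0] <- 0L
  }
  out
}

#' One-call patient-level simulation sample
#'
#' Composes [generate_covariates()], [assign_treatment()] and
#' [simulate_outcome_values()] without materializing claims tables; the path
#' used by Monte-Carlo recovery and calibration studies.
#'
#' @param config A [claims_sim_config()].
#' @param seed Overrides the config seed.
#' @return A list: `covariates`, `treated`, `true_ps`, `outcomes`, `design`
#'   (the true-confounder design matrix, suitable for [fit_propensity()]).
#' @export
simulate_analysis_sample <- function(config, seed = config$seed) {
  gc_ <- generate_covariates(config, seed + 1, tables = FALSE)
  tr <- assign_treatment(gc_$covariates, config$beta, seed + 2)
  out <- simulate_outcome_values(gc_$covariates, tr$treated, config, seed + 3)
  list(covariates = gc_$covariates, treated = tr$treated, true_ps = tr$true_ps,
       outcomes = out, design = treatment_design(gc_$covariates))
}

scz_codes <- function() c("295.30", "295.32", "295.62", "295.70", "295.90")
mh_extra_codes <- function() c("296.30", "300.00", "309.81", "311", "298.9",
                               "301.22", "296.90", "300.4")
como_codes <- function() {
  c(cardiovascular = "428.0", diabetes = "250.00", obesity = "278.00",
    drug_abuse = "304.90", hepatitis_c = "070.54", hiv_aids = "042")
}
extra_cci_codes <- function() c(copd = "496", renal = "585")

#' Generate a full synthetic claims bundle with ground truth
#'
#' Materializes the patient-level simulation into the four claims tables:
#' baseline diagnosis and utilization claims (schizophrenia diagnoses,
#' comorbidity codes, admissions, baseline costs), baseline non-index
#' psychiatric fills (spaced so they never qualify as initiations), the
#' index-agent renewal fills from the first follow-up day, concomitant
#' psychiatric fills, and follow-up medical claims whose summed standardized
#' cost reproduces the drawn annual medical cost exactly. Claims falling in
#' configured enrollment holes are dropped (no coverage, no claim), so the
#' bundle passes strict validation.
#'
#' @param config A [claims_sim_config()].
#' @return A list: `bundle` (a `claims_bundle`) and `truth` (per-patient
#'   treated label, true assignment probability, injected effects and
#'   adherence latent).
#' @export
generate_bundle <- function(config) {
  gc_ <- generate_covariates(config, config$seed + 1)
  covs <- gc_$covariates
  tr <- assign_treatment(covs, config$beta, config$seed + 2)
  outcomes <- simulate_outcome_values(covs, tr$treated, config, config$seed + 3)
  set.seed(config$seed + 4)
  n <- nrow(covs)
  cpi <- cpi_medical()
  map <- default_agent_map()
  oaa_codes <- map$agent_code[map$agent_class %in% oaa_classes()]
  ap_bg_codes <- map$agent_code[map$agent_class %in%
                                  c("typical_oral_ap", "typical_lai",
                                    "other_atypical_lai")]
  support_codes <- map$agent_code[map$agent_class %in% psych_support_classes()]
  class_of <- stats::setNames(map$agent_class, map$agent_code)
  branded_of <- stats::setNames(map$branded, map$agent_code)

  index_agent <- ifelse(tr$treated, "PP1M",
                        sample(oaa_codes, n, replace = TRUE))
  year_of <- function(day_num) {
    as.integer(format(as.Date(day_num, origin = "1970-01-01"), "%Y"))
  }

  ph_acc <- vector("list", n)
  md_acc <- vector("list", n)
  for (i in seq_len(n)) {
    index <- as.numeric(covs$index_date[i])
    arm <- if (tr$treated[i]) "pp1m" else "oaa"
    agent <- index_agent[i]
    as_medical <- tr$treated[i] && covs$pp1m_medical[i]

    # pharmacy accumulators: absolute day numbers, agent codes, paid amounts
    p_day <- numeric(); p_agent <- character(); p_paid <- numeric()

    # --- index-agent fills ---
    fills <- generate_fills(arm, config$fill, covs$adherence_z[i],
                            no_second_fill = covs$no_second_fill[i])
    f_days <- index + fills$day
    price <- config$fill_price[[arm]]
    if (!as_medical) {
      p_day <- c(p_day, f_days)
      p_agent <- c(p_agent, rep(agent, length(f_days)))
      p_paid <- c(p_paid, round(price * runif(length(f_days), 0.9, 1.1), 2))
    }

    # --- baseline psychiatric fills (never two within 90 days per agent) ---
    if (covs$prior_ap[i]) {
      agents <- sample(setdiff(c(oaa_codes, ap_bg_codes), agent),
                       sample(1:2, 1))
      for (a in agents) {
        k <- sample(1:3, 1)
        days <- -sample(250:360, 1) + (seq_len(k) - 1L) * 120L
        days <- days[days <= -1L]
        p_day <- c(p_day, index + days)
        p_agent <- c(p_agent, rep(a, length(days)))
        p_paid <- c(p_paid, round(config$fill_price[["background"]] *
                                    runif(length(days), 0.8, 1.2), 2))
      }
    }
    if (covs$baseline_support[i]) {
      a <- sample(support_codes, 1)
      days <- -sample(30:330, sample(2:5, 1))
      p_day <- c(p_day, index + days)
      p_agent <- c(p_agent, rep(a, length(days)))
      p_paid <- c(p_paid, round(config$fill_price[["background"]] *
                                  runif(length(days), 0.8, 1.2), 2))
    }

    # --- concomitant follow-up fills ---
    if (runif(1) < config$p_conc_ap) {
      a <- sample(setdiff(c(oaa_codes, ap_bg_codes), agent), 1)
      days <- sample(0:200, 1) + seq(0, by = 35, length.out = sample(2:6, 1))
      days <- days[days <= 364]
      p_day <- c(p_day, index + days)
      p_agent <- c(p_agent, rep(a, length(days)))
      p_paid <- c(p_paid, round(config$fill_price[["background"]] *
                                  runif(length(days), 0.8, 1.2), 2))
    }
    if (runif(1) < config$p_conc_support) {
      a <- sample(support_codes, 1)
      days <- sample(0:150, 1) + seq(0, by = 32, length.out = sample(3:8, 1))
      days <- days[days <= 364]
      p_day <- c(p_day, index + days)
      p_agent <- c(p_agent, rep(a, length(days)))
      p_paid <- c(p_paid, round(config$fill_price[["background"]] *
                                  runif(length(days), 0.8, 1.2), 2))
    }

    # medical accumulators
    m_day <- numeric(); m_los <- integer(); m_cat <- character()
    m_dx <- character(); m_agent <- character()
    add_md <- function(day, category, codes, los = 0L, agent_code = "") {
      k <- length(day)
      m_day <<- c(m_day, index + day)
      m_los <<- c(m_los, rep_len(as.integer(los), k))
      m_cat <<- c(m_cat, rep_len(category, k))
      m_dx <<- c(m_dx, rep_len(codes, k))
      m_agent <<- c(m_agent, rep_len(agent_code, k))
    }

    # patients flagged as lacking a confirmed diagnosis carry a single
    # schizophrenia-coded claim date; their other claims use other codes
    psy_pool <- if (covs$missing_scz[i]) mh_extra_codes() else
      c(scz_codes(), mh_extra_codes())
    n_scz <- if (covs$missing_scz[i]) 1L else 2L
    add_md(-sample(10:350, n_scz), "outpatient",
           sample(scz_codes(), n_scz, replace = TRUE))
    base_codes <- character()
    for (nm in names(config$como_prev)) {
      if (covs[[paste0("cm_", nm)]][i]) base_codes <- c(base_codes, como_codes()[[nm]])
    }
    for (nm in names(config$extra_cci_prev)) {
      if (covs[[paste0("cx_", nm)]][i]) base_codes <- c(base_codes, extra_cci_codes()[[nm]])
    }
    base_codes <- c(base_codes, sample(mh_extra_codes(), sample(0:5, 1)))
    if (length(base_codes) > 0) {
      add_md(-sample(10:350, length(base_codes), replace = TRUE), "outpatient",
             base_codes)
    }
    if (covs$n_mhi_baseline[i] > 0) {
      k <- covs$n_mhi_baseline[i]
      add_md(-sample(10:340, k, replace = TRUE), "mhi_admission",
             sample(psy_pool, k, replace = TRUE), los = sample(2:9, k, replace = TRUE))
    }
    if (covs$n_mhi1_baseline[i] > 0) {
      k <- covs$n_mhi1_baseline[i]
      add_md(-sample(10:350, k, replace = TRUE), "mhi_1day",
             sample(psy_pool, k, replace = TRUE))
    }
    n_base <- length(m_day)
    base_cost <- rgamma(1, shape = config$baseline_cost_shape,
                        scale = (config$baseline_cost_base *
                                   (1 + 0.3 * covs$n_mhi_baseline[i])) /
                          config$baseline_cost_shape) * 12
    m_paid <- if (n_base > 0) {
      wts <- rexp(n_base)
      round(base_cost * wts / sum(wts), 2)
    } else numeric()

    # --- follow-up medical claims carrying the outcome cost ---
    for (cat in names(config$rate_base)) {
      k <- outcomes[[paste0("ev_", cat)]][i]
      if (k == 0) next
      los_col <- paste0("days_", cat)
      total_days <- if (los_col %in% names(outcomes)) outcomes[[los_col]][i] else k
      base_los <- if (cat %in% names(config$los_mean) && cat != "mhi_1day") {
        dd <- rep(total_days %/% k, k)
        extra <- total_days %% k
        if (extra > 0) dd[seq_len(extra)] <- dd[seq_len(extra)] + 1L
        pmax(dd - 1L, 0L)
      } else rep(0L, k)
      add_md(vapply(base_los, function(l) sample(0:(364 - l), 1), numeric(1)),
             cat, sample(psy_pool, k, replace = TRUE), los = base_los)
    }
    if (as_medical) {  # provider-administered index doses as medical claims
      add_md(f_days - index, "other",
             sample(psy_pool, length(f_days), replace = TRUE),
             agent_code = "PP1M")
    }
    annual_cost <- outcomes$monthly_medical_cost[i] * 12
    if (annual_cost > 0 && length(m_day) == n_base) {
      add_md(sample(0:364, 1), "other", sample(mh_extra_codes(), 1))
    }
    n_fu <- length(m_day) - n_base
    fu_paid <- numeric(n_fu)
    if (n_fu > 0 && annual_cost > 0) {
      # paid in service-year dollars so that standardization back to the
      # target year recovers the drawn cost exactly
      wts <- rexp(n_fu)
      yrs <- year_of(m_day[(n_base + 1):length(m_day)])
      ratio <- cpi[as.character(yrs)] /
        cpi[[as.character(2015)]]
      fu_paid <- annual_cost * wts / sum(wts) * unname(ratio)
    }
    m_paid <- c(m_paid, fu_paid)

    ph_acc[[i]] <- list(day = p_day, agent = p_agent, paid = p_paid)
    md_acc[[i]] <- list(day = m_day, los = m_los, cat = m_cat, dx = m_dx,
                        agent = m_agent, paid = m_paid)
  }

  ph_n <- vapply(ph_acc, function(x) length(x$day), integer(1))
  ph_day <- unlist(lapply(ph_acc, `[[`, "day"), use.names = FALSE)
  ph_agent_v <- unlist(lapply(ph_acc, `[[`, "agent"), use.names = FALSE)
  ph_dates <- as.Date(ph_day, origin = "1970-01-01")
  pharmacy <- tibble::tibble(
    patient_id = rep(covs$patient_id, ph_n),
    dispense_date = ph_dates,
    agent_code = ph_agent_v,
    agent_class = unname(class_of[ph_agent_v]),
    days_supply = config$fill$days_supply,
    paid_amount = unlist(lapply(ph_acc, `[[`, "paid"), use.names = FALSE),
    branded = unname(branded_of[ph_agent_v]),
    service_year = as.integer(format(ph_dates, "%Y")))

  md_n <- vapply(md_acc, function(x) length(x$day), integer(1))
  md_day <- unlist(lapply(md_acc, `[[`, "day"), use.names = FALSE)
  md_los <- unlist(lapply(md_acc, `[[`, "los"), use.names = FALSE)
  md_dates <- as.Date(md_day, origin = "1970-01-01")
  md_agent_v <- unlist(lapply(md_acc, `[[`, "agent"), use.names = FALSE)
  medical <- tibble::tibble(
    patient_id = rep(covs$patient_id, md_n),
    start_date = md_dates,
    end_date = md_dates + md_los,
    service_category = unlist(lapply(md_acc, `[[`, "cat"), use.names = FALSE),
    dx_codes = unlist(lapply(md_acc, `[[`, "dx"), use.names = FALSE),
    paid_amount = unlist(lapply(md_acc, `[[`, "paid"), use.names = FALSE),
    agent_code = md_agent_v,
    branded = md_agent_v == "PP1M",
    service_year = as.integer(format(md_dates, "%Y")))

  enrollment <- gc_$enrollment
  patients <- gc_$patients

  # claims falling into configured enrollment holes are dropped (no
  # coverage, no claim), so the bundle passes strict validation
  keep_ph <- covered_by_enrollment(pharmacy$patient_id, pharmacy$dispense_date,
                                   enrollment)
  keep_md <- covered_by_enrollment(medical$patient_id, medical$start_date,
                                   enrollment)
  bundle <- claims_bundle(patients, enrollment, pharmacy[keep_ph, ],
                          medical[keep_md, ], strict = TRUE)
  truth <- tibble::tibble(
    patient_id = covs$patient_id, treated = tr$treated,
    true_ps = tr$true_ps, index_agent = index_agent,
    index_date = covs$index_date,
    delta_true = config$delta_true, rr_true = config$rr_true,
    adherence_z = covs$adherence_z,
    monthly_medical_cost = outcomes$monthly_medical_cost
  )
  list(bundle = bundle, truth = truth)
}

#' Convenience wrapper: default-config synthetic bundle
#'
#' @param n_patients Number of patients.
#' @param seed Master seed.
#' @param ... Config overrides passed to [claims_sim_config()].
#' @return See [generate_bundle()].
#' @export
simulate_bundle <- function(n_patients = 500, seed = 1, ...) {
  generate_bundle(claims_sim_config(n_patients = n_patients, seed = seed, ...))
}
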