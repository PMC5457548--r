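# New-user cohort construction: index events (two qualifying claims within 90
# days, 12-month agent-specific washout), inclusion criteria, the
# recently-diagnosed subcohort, and the baseline covariate record feeding the
# propensity model.

#' Age in completed years at a date
#'
#' @param birth_date,on_date Date vectors (recycled).
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, on_date) {
  b <- as.POSIXlt(birth_date); d <- as.POSIXlt(on_date)
  age <- d$year - b$year
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - before_birthday)
}

index_claim_stream <- function(bundle, agent_map) {
  class_of <- stats::setNames(agent_map$agent_class, agent_map$agent_code)
  ph <- bundle$pharmacy
  ev <- tibble::tibble(patient_id = ph$patient_id, date = ph$dispense_date,
                       agent_code = ph$agent_code)
  md <- bundle$medical
  md <- md[!is.na(md$agent_code) & nzchar(md$agent_code), ]
  if (nrow(md) > 0) {
    keep <- class_of[md$agent_code] == "pp1m" & !is.na(class_of[md$agent_code])
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      patient_id = md$patient_id[keep], date = md$start_date[keep],
      agent_code = md$agent_code[keep]))
  }
  ev$agent_class <- unname(class_of[ev$agent_code])
  # only agents that can define a treatment cohort
  ev[!is.na(ev$agent_class) & ev$agent_class %in% c("pp1m", oaa_classes()), ]
}

# Earliest qualifying initiation date for one agent's claim dates: a date D at
# or after accrual with a second claim in [D, D+90] and no claim in
# [D-365, D-1]. Dates carry row multiplicity (two same-day claims qualify).
first_initiation <- function(dates, accrual_start) {
  dates <- sort(dates)
  for (D in unique(dates[dates >= accrual_start])) {
    if (any(dates >= D - 365 & dates <= D - 1)) next       # washout violated
    if (sum(dates >= D & dates <= D + 90) >= 2) return(D)  # second claim found
  }
  NULL
}

#' Find index events
#'
#' For each patient, the earliest date on or after `accrual_start` at which an
#' eligible agent has a second qualifying claim within 90 days and no claim
#' for that same agent in the preceding 12 months. The treated index agent is
#' identifiable from pharmacy or medical claims; comparator agents from
#' pharmacy claims only. When a treated and a comparator candidate tie on the
#' same earliest date, the treated agent is retained.
#'
#' @param bundle A `claims_bundle`.
#' @param accrual_start First allowed index date (default `"2009-09-01"`).
#' @param agent_map Agent code/class map.
#' @return A tibble (`patient_id`, `index_date`, `index_agent`, `cohort`);
#'   patients with no qualifying initiation are absent.
#' @export
find_index_events <- function(bundle, accrual_start = as.Date("2009-09-01"),
                              agent_map = default_agent_map()) {
  accrual_start <- as.Date(accrual_start)
  ev <- index_claim_stream(bundle, agent_map)
  if (nrow(ev) == 0) {
    return(tibble::tibble(patient_id = character(), index_date = as.Date(character()),
                          index_agent = character(), cohort = character()))
  }
  out <- lapply(split(ev, ev$patient_id), function(pe) {
    cands <- lapply(split(pe$date, pe$agent_code), first_initiation, accrual_start)
    cands <- cands[!vapply(cands, is.null, logical(1))]
    if (length(cands) == 0) return(NULL)
    d <- as.Date(unname(vapply(cands, as.numeric, numeric(1))),
                 origin = "1970-01-01")
    agents <- names(cands)
    classes <- pe$agent_class[match(agents, pe$agent_code)]
    best <- which(d == min(d))
    if (length(best) > 1) {  # tie: treated LAI preferred, then alphabetical
      pp <- best[classes[best] == "pp1m"]
      best <- if (length(pp) > 0) pp[1] else best[order(agents[best])][1]
    }
    tibble::tibble(patient_id = pe$patient_id[1], index_date = d[best],
                   index_agent = agents[best],
                   cohort = ifelse(classes[best] == "pp1m", "PP1M", "OAA"))
  })
  dplyr::bind_rows(out)
}

# Is [start, end] fully covered by the union of a patient's enrollment spans?
window_enrolled <- function(spans, start, end) {
  if (is.null(spans) || nrow(spans) == 0) return(FALSE)
  iv <- merge_intervals(new_intervals(as.integer(spans$start_date),
                                      as.integer(spans$end_date)))
  any(iv$start <= as.integer(start) & iv$end >= as.integer(end))
}

#' Apply inclusion criteria to index events
#'
#' Evaluates the five inclusion criteria per event: (a) a qualifying
#' initiation exists (true by construction for rows from
#' [find_index_events()]), (b) at least two distinct claim dates bearing a
#' schizophrenia diagnosis (ICD-9 295 prefix) anywhere in the data period,
#' (c) age at least 18 at index, (d) continuous enrollment over the 365 days
#' before index, and (e) continuous enrollment over the 365 days from index.
#'
#' @param bundle A `claims_bundle`.
#' @param events Index events.
#' @return `events` with logical columns `crit_a` .. `crit_e`, `included`, and
#'   `exclusion_reason` (first failed criterion, `NA` when included).
#' @export
apply_inclusion <- function(bundle, events) {
  dx <- expand_dx(bundle$medical)
  dx <- dx[match_dx(dx$code, "295.xx"), ]
  scz_dates <- vapply(split(dx$date, dx$patient_id),
                      function(d) length(unique(d)), integer(1))
  spans <- split(bundle$enrollment, bundle$enrollment$patient_id)
  birth <- stats::setNames(bundle$patients$birth_date, bundle$patients$patient_id)

  n_scz <- ifelse(is.na(scz_dates[events$patient_id]), 0L,
                  scz_dates[events$patient_id])
  events$crit_a <- rep(TRUE, nrow(events))
  events$crit_b <- unname(n_scz >= 2L)
  events$crit_c <- age_at(birth[events$patient_id], events$index_date) >= 18L
  events$crit_d <- vapply(seq_len(nrow(events)), function(i) {
    window_enrolled(spans[[events$patient_id[i]]],
                    events$index_date[i] - 365, events$index_date[i] - 1)
  }, logical(1))
  events$crit_e <- vapply(seq_len(nrow(events)), function(i) {
    window_enrolled(spans[[events$patient_id[i]]],
                    events$index_date[i], events$index_date[i] + 364)
  }, logical(1))
  events$included <- events$crit_a & events$crit_b & events$crit_c &
    events$crit_d & events$crit_e
  reasons <- c(crit_a = "no-index-event", crit_b = "schizophrenia-dx",
               crit_c = "age-under-18", crit_d = "pre-enrollment",
               crit_e = "post-enrollment")
  flag_mat <- as.matrix(events[paste0("crit_", letters[1:5])])
  events$exclusion_reason <- apply(flag_mat, 1, function(f) {
    bad <- which(!f)
    if (length(bad) == 0) NA_character_ else unname(reasons[bad[1]])
  })
  events
}

#' Flag the recently-diagnosed subcohort
#'
#' Recently diagnosed is proxied by age 18-25 (completed years, inclusive on
#' both ends) at the index date.
#'
#' @param events Index events (typically after [apply_inclusion()]).
#' @param patients Patient table providing birth dates.
#' @return `events` with `age_at_index` and `recently_diagnosed` columns.
#' @export
assign_subcohorts <- function(events, patients) {
  birth <- stats::setNames(patients$birth_date, patients$patient_id)
  events$age_at_index <- age_at(birth[events$patient_id], events$index_date)
  events$recently_diagnosed <- events$age_at_index >= 18L & events$age_at_index <= 25L
  events
}

mh_dx_prefixes <- function() as.character(290:319)

#' Build the baseline covariate record for the propensity model
#'
#' All fields are computed from claims in the 365-day window before the index
#' date. Baseline any-antipsychotic PDC uses a 365-day denominator and is
#' categorized as zero, below 0.8, or at least 0.8 (the latter two only among
#' patients with positive coverage, mirroring how the categories are defined
#' as shares of patients with any coverage). Costs are standardized to the
#' target year and divided by 12.
#'
#' @param bundle A `claims_bundle`.
#' @param events Included index events.
#' @param agent_map Agent code/class map.
#' @param quan_map,como_map Code lists ([quan_cci_map()], [comorbidity_map()]).
#' @param cpi CPI table ([cpi_medical()]).
#' @param target_year Cost reference year (default 2015).
#' @return A tibble, one covariate row per event.
#' @export
build_baseline_covariates <- function(bundle, events,
                                      agent_map = default_agent_map(),
                                      quan_map = quan_cci_map(),
                                      como_map = comorbidity_map(),
                                      cpi = cpi_medical(), target_year = 2015) {
  pts <- bundle$patients
  pidx <- match(events$patient_id, pts$patient_id)
  dx_all <- expand_dx(bundle$medical)
  dx_by_patient <- split(dx_all, dx_all$patient_id)
  med_by_patient <- split(bundle$medical, bundle$medical$patient_id)
  ph_by_patient <- split(bundle$pharmacy, bundle$pharmacy$patient_id)
  spans <- split(bundle$enrollment, bundle$enrollment$patient_id)
  como_names <- unique(como_map$name)

  rows <- lapply(seq_len(nrow(events)), function(i) {
    pid <- events$patient_id[i]
    index <- events$index_date[i]
    w0 <- index - 365; w1 <- index - 1

    dx <- dx_by_patient[[pid]]
    dx_codes <- if (is.null(dx)) character() else dx$code[dx$date >= w0 & dx$date <= w1]
    md <- med_by_patient[[pid]]
    md <- if (is.null(md)) bundle$medical[0, ] else md[md$start_date >= w0 & md$start_date <= w1, ]
    ph <- ph_by_patient[[pid]]
    ph <- if (is.null(ph)) bundle$pharmacy[0, ] else ph[ph$dispense_date >= w0 & ph$dispense_date <= w1, ]
    sp <- spans[[pid]]
    overlap <- if (is.null(sp)) sp else sp[sp$start_date <= w1 & sp$end_date >= w0, ]

    stripped <- gsub(".", "", dx_codes, fixed = TRUE)
    mh <- unique(stripped[substr(stripped, 1, 3) %in% mh_dx_prefixes()])
    psych <- ph$agent_class %in% c(ap_classes(), psych_support_classes())
    ap <- ph$agent_class %in% ap_classes()

    rel <- as.integer(ph$dispense_date - w0)
    cal_ap <- coverage_intervals(rel[ap], ph$days_supply[ap], 0L, 364L)
    pdc <- compute_pdc(cal_ap)
    cals <- lapply(split(which(ap), ph$agent_code[ap]), function(j) {
      coverage_intervals(rel[j], ph$days_supply[j], 0L, 364L)
    })
    classes <- stats::setNames(
      agent_map$agent_class[match(names(cals), agent_map$agent_code)], names(cals))

    como <- comorbidity_flags(dx_codes, como_map)
    med_cost <- sum(standardize_costs(md$paid_amount, md$service_year, cpi, target_year))
    ph_cost <- sum(standardize_costs(ph$paid_amount, ph$service_year, cpi, target_year))

    tibble::tibble(
      patient_id = pid,
      age_at_index = age_at(pts$birth_date[pidx[i]], index),
      sex = pts$sex[pidx[i]], race = pts$race[pidx[i]],
      state = pts$state[pidx[i]], region = pts$region[pidx[i]],
      capitated = !is.null(overlap) && any(overlap$capitated),
      dual_coverage = !is.null(overlap) && any(overlap$dual_coverage),
      index_year = as.integer(format(index, "%Y")),
      index_quarter = (as.integer(format(index, "%m")) - 1L) %/% 3L + 1L,
      quan_cci = compute_quan_cci(dx_codes, quan_map),
      n_unique_mh_dx = length(mh),
      n_unique_psych_agents = length(unique(ph$agent_code[psych])),
      ap_use = any(ap),
      ap_typical_oral = any(ph$agent_class == "typical_oral_ap"),
      ap_atypical_oral = any(ph$agent_class %in% oaa_classes()),
      ap_typical_lai = any(ph$agent_class == "typical_lai"),
      ap_atypical_lai = any(ph$agent_class %in% c("pp1m", "other_atypical_lai")),
      baseline_pdc = pdc,
      baseline_pdc_cat = if (pdc == 0) "pdc_zero" else if (pdc < 0.8) "pdc_lt80" else "pdc_ge80",
      ap_polypharmacy = detect_polypharmacy(cals, classes, mode = "ap_ap"),
      use_anxiolytic = any(ph$agent_class == "anxiolytic"),
      use_antidepressant = any(ph$agent_class == "antidepressant"),
      use_mood_stabilizer = any(ph$agent_class == "mood_stabilizer"),
      cm_cardiovascular = como[["cardiovascular"]],
      cm_diabetes = como[["diabetes"]],
      cm_obesity = como[["obesity"]],
      cm_drug_abuse = como[["drug_abuse"]],
      cm_hepatitis_c = como[["hepatitis_c"]],
      cm_hiv_aids = como[["hiv_aids"]],
      n_mhi_admissions = sum(md$service_category == "mhi_admission"),
      n_mhi_1day = sum(md$service_category == "mhi_1day"),
      baseline_monthly_medical = med_cost / 12,
      baseline_monthly_pharmacy = ph_cost / 12,
      baseline_monthly_total = (med_cost + ph_cost) / 12
    )
  })
  dplyr::bind_rows(rows)
}
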