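# Interval algebra over medication coverage. All intervals are closed integer
# day intervals [start, end], kept sorted and pairwise disjoint; days are
# offsets relative to the patient's index date (0 = index). The observation
# window is [0, 364].

new_intervals <- function(start = integer(), end = integer()) {
  tibble::tibble(start = as.integer(start), end = as.integer(end))
}

# Merge sorted-or-not intervals into disjoint ones; intervals separated by at
# most `bridge` uncovered days are joined (bridge = 0 joins abutting ones).
merge_intervals <- function(iv, bridge = 0L) {
  if (nrow(iv) <= 1) return(iv)
  o <- order(iv$start, iv$end)
  s <- iv$start[o]; e <- iv$end[o]
  out_s <- s[1]; out_e <- e[1]; k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[k] + 1L + bridge) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  new_intervals(out_s[seq_len(k)], out_e[seq_len(k)])
}

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(new_intervals())
  i <- 1L; j <- 1L; out_s <- integer(); out_e <- integer()
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s <= e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  new_intervals(out_s, out_e)
}

covered_days <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  sum(iv$end - iv$start + 1L)
}

#' Coverage calendar from pharmacy fills
#'
#' Each fill covers the closed interval from its dispense day through
#' `days_supply - 1` days later. Overlapping supply is de-duplicated by union
#' (calendar-day coverage); supply is not shifted forward. Intervals are
#' clipped to the observation window.
#'
#' @param dispense Integer vector of dispense days (offsets; index = 0).
#' @param days_supply Integer vector of days supplied per fill.
#' @param win_start,win_end Closed observation window (defaults `[0, 364]`).
#' @return A tibble of disjoint intervals with columns `start`, `end`.
#' @export
coverage_intervals <- function(dispense, days_supply, win_start = 0L, win_end = 364L) {
  stopifnot(length(dispense) == length(days_supply))
  if (length(dispense) == 0) return(new_intervals())
  s <- pmax(as.integer(dispense), as.integer(win_start))
  e <- pmin(as.integer(dispense) + as.integer(days_supply) - 1L, as.integer(win_end))
  keep <- s <= e
  merge_intervals(new_intervals(s[keep], e[keep]), bridge = 0L)
}

#' Proportion of days covered
#'
#' Unique covered calendar days divided by the window length (365 by default,
#' the fixed 12-month observation period).
#'
#' @param calendar A coverage calendar from [coverage_intervals()].
#' @param window_length Denominator in days.
#' @return A fraction in `[0, 1]`.
#' @export
compute_pdc <- function(calendar, window_length = 365L) {
  covered_days(calendar) / window_length
}

#' Continuous exposure to the index agent
#'
#' Walks index-agent fills in date order; the exposure chain ends at the
#' supply-end of the first fill whose successor (if any) starts more than
#' `permissible_gap` days after that supply-end. Duration runs from the index
#' date to the chain end, clipped to the window.
#'
#' @param dispense,days_supply Fill days (offsets, first fill at 0) and supply.
#' @param permissible_gap Maximum allowed days between a fill's supply-end and
#'   the next fill (default 90).
#' @param win_end End of the observation window.
#' @return A list with `duration` (days) and `n_dispensings` (fills in window).
#' @export
continuous_exposure <- function(dispense, days_supply, permissible_gap = 90L,
                                win_end = 364L) {
  o <- order(dispense)
  d <- as.integer(dispense[o]); s <- as.integer(days_supply[o])
  keep <- d >= 0L & d <= win_end
  d <- d[keep]; s <- s[keep]
  if (length(d) == 0) return(list(duration = 0L, n_dispensings = 0L))
  chain_end <- d[1] + s[1] - 1L
  for (i in seq_along(d)[-1]) {
    if (d[i] > chain_end + permissible_gap) break
    chain_end <- d[i] + s[i] - 1L
  }
  list(duration = min(chain_end, win_end) + 1L, n_dispensings = length(d))
}

# Uncovered runs of a merged calendar within the window: lengths plus a flag
# marking the run that touches the window end.
uncovered_runs <- function(calendar, win_start = 0L, win_end = 364L) {
  iv <- merge_intervals(calendar)
  iv <- iv[iv$end >= win_start & iv$start <= win_end, ]
  if (nrow(iv) == 0) {
    return(tibble::tibble(length = win_end - win_start + 1L, terminal = TRUE))
  }
  iv$start <- pmax(iv$start, win_start); iv$end <- pmin(iv$end, win_end)
  bounds_s <- c(win_start, iv$end + 1L)
  bounds_e <- c(iv$start - 1L, win_end)
  len <- bounds_e - bounds_s + 1L
  keep <- len > 0L
  tibble::tibble(length = len[keep],
                 terminal = (bounds_s == iv$end[nrow(iv)] + 1L)[keep])
}

#' Persistence flags at supply-gap thresholds
#'
#' A patient is persistent at threshold `g` when no uncovered run of at least
#' `g` days occurs in the observation window. Runs include the days before the
#' first covered day and, when `count_terminal_gap` (the default), the run
#' from the last covered day to the window end.
#'
#' @param calendar A coverage calendar (merged intervals).
#' @param thresholds Gap thresholds in days.
#' @param count_terminal_gap Count the trailing uncovered run (default `TRUE`).
#' @param win_start,win_end Observation window.
#' @return Named logical vector, one flag per threshold.
#' @export
persistence_flags <- function(calendar, thresholds = c(30L, 60L, 90L),
                              count_terminal_gap = TRUE,
                              win_start = 0L, win_end = 364L) {
  runs <- uncovered_runs(calendar, win_start, win_end)
  if (!count_terminal_gap) runs <- runs[!runs$terminal, ]
  vapply(stats::setNames(thresholds, paste0("no_gap_", thresholds)),
         function(g) !any(runs$length >= g), logical(1))
}

#' Detect antipsychotic or psychiatric polypharmacy
#'
#' Per agent, coverage gaps of at most `bridge_gap` days are bridged; the flag
#' is raised when the bridged calendars of a qualifying agent pair intersect
#' in a run of at least `min_overlap` consecutive days. Qualifying pairs are
#' two distinct antipsychotic agents (`mode = "ap_ap"`) or an antipsychotic
#' with an anxiolytic, antidepressant or mood stabilizer (`mode = "ap_other"`).
#'
#' @param calendars Named list of coverage calendars, one per agent code.
#' @param classes Named character vector mapping agent codes to agent classes.
#' @param min_overlap Minimum consecutive overlap days (default 60).
#' @param bridge_gap Maximum per-agent coverage gap bridged (default 7).
#' @param mode `"ap_ap"` or `"ap_other"`.
#' @return Single logical flag.
#' @export
detect_polypharmacy <- function(calendars, classes, min_overlap = 60L,
                                bridge_gap = 7L, mode = c("ap_ap", "ap_other")) {
  mode <- match.arg(mode)
  agents <- names(calendars)
  ap <- agents[classes[agents] %in% ap_classes()]
  other <- agents[classes[agents] %in% psych_support_classes()]
  pairs <- if (mode == "ap_ap") {
    if (length(ap) < 2) return(FALSE)
    utils::combn(ap, 2, simplify = FALSE)
  } else {
    if (length(ap) < 1 || length(other) < 1) return(FALSE)
    unlist(lapply(ap, function(a) lapply(other, function(b) c(a, b))),
           recursive = FALSE)
  }
  bridged <- lapply(calendars, merge_intervals, bridge = bridge_gap)
  for (p in pairs) {
    ov <- intersect_intervals(bridged[[p[1]]], bridged[[p[2]]])
    if (nrow(ov) > 0 && any(ov$end - ov$start + 1L >= min_overlap)) return(TRUE)
  }
  FALSE
}

# Fills usable for coverage: pharmacy claims plus provider-administered index
# LAI doses appearing as medical claims (imputed once-monthly supply).
all_fills <- function(bundle, agent_map, pp1m_days_supply = 30L) {
  ph <- bundle$pharmacy
  fills <- tibble::tibble(
    patient_id = ph$patient_id,
    date = ph$dispense_date,
    agent_code = ph$agent_code,
    agent_class = ph$agent_class,
    days_supply = ph$days_supply
  )
  md <- bundle$medical
  md <- md[!is.na(md$agent_code) & nzchar(md$agent_code), ]
  if (nrow(md) > 0) {
    cls <- agent_map$agent_class[match(md$agent_code, agent_map$agent_code)]
    keep <- !is.na(cls) & cls == "pp1m"
    if (any(keep)) {
      fills <- dplyr::bind_rows(fills, tibble::tibble(
        patient_id = md$patient_id[keep],
        date = md$start_date[keep],
        agent_code = md$agent_code[keep],
        agent_class = "pp1m",
        days_supply = pp1m_days_supply
      ))
    }
  }
  fills$days_supply[fills$agent_class == "pp1m"] <- pp1m_days_supply
  fills
}

#' Per-patient treatment-pattern summary over the 12-month follow-up
#'
#' Computes, for each index event, the exposure outcomes of the analysis:
#' continuous-exposure duration and dispensings of the index agent, PDC and
#' adherence (PDC >= 0.8) on the index agent and on any antipsychotic,
#' persistence flags at 30/60/90-day gaps for both, antipsychotic and
#' psychiatric polypharmacy, and concomitant medication-class use (excluding
#' the index agent).
#'
#' @param bundle A `claims_bundle`.
#' @param events Index events (`patient_id`, `index_date`, `index_agent`,
#'   `cohort`), typically the included rows from [find_index_events()].
#' @param agent_map Agent code/class map.
#' @param permissible_gap Continuous-exposure gap allowance in days.
#' @param count_terminal_gap Terminal-gap mode for persistence.
#' @param pp1m_days_supply Imputed supply for once-monthly LAI claims.
#' @return A tibble, one row per event, with the exposure summary fields.
#' @export
exposure_summary <- function(bundle, events, agent_map = default_agent_map(),
                             permissible_gap = 90L, count_terminal_gap = TRUE,
                             pp1m_days_supply = 30L) {
  fills <- all_fills(bundle, agent_map, pp1m_days_supply)
  fills_by_patient <- split(fills, fills$patient_id)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    pid <- events$patient_id[i]
    index <- events$index_date[i]
    agent <- events$index_agent[i]
    f <- fills_by_patient[[pid]]
    if (is.null(f)) f <- fills[0, ]
    rel <- as.integer(f$date - index)
    in_reach <- rel + f$days_supply - 1L >= 0L & rel <= 364L

    idx <- f$agent_code == agent
    cal_index <- coverage_intervals(rel[idx & in_reach], f$days_supply[idx & in_reach])
    ap <- f$agent_class %in% ap_classes()
    cal_any_ap <- coverage_intervals(rel[ap & in_reach], f$days_supply[ap & in_reach])

    ce <- continuous_exposure(rel[idx], f$days_supply[idx],
                              permissible_gap = permissible_gap)
    pdc_i <- compute_pdc(cal_index)
    pdc_a <- compute_pdc(cal_any_ap)
    pers_i <- persistence_flags(cal_index, count_terminal_gap = count_terminal_gap)
    pers_a <- persistence_flags(cal_any_ap, count_terminal_gap = count_terminal_gap)

    # per-agent calendars for polypharmacy (all psychiatric agents in window)
    psych <- (ap | f$agent_class %in% psych_support_classes()) & in_reach
    cals <- lapply(split(which(psych), f$agent_code[psych]), function(j) {
      coverage_intervals(rel[j], f$days_supply[j])
    })
    classes <- stats::setNames(
      agent_map$agent_class[match(names(cals), agent_map$agent_code)], names(cals))
    poly_ap <- detect_polypharmacy(cals, classes, mode = "ap_ap")
    poly_psy <- detect_polypharmacy(cals, classes, mode = "ap_other")

    conc <- f[in_reach & f$agent_code != agent, ]
    cls_flag <- function(x) any(conc$agent_class %in% x)
    tibble::tibble(
      patient_id = pid, cohort = events$cohort[i],
      duration_continuous_exposure = ce$duration,
      n_dispensings = ce$n_dispensings,
      pdc_index = pdc_i, pdc_any_ap = pdc_a,
      adherent_index = pdc_i >= 0.8, adherent_any_ap = pdc_a >= 0.8,
      persist30_index = pers_i[["no_gap_30"]],
      persist60_index = pers_i[["no_gap_60"]],
      persist90_index = pers_i[["no_gap_90"]],
      persist30_any_ap = pers_a[["no_gap_30"]],
      persist60_any_ap = pers_a[["no_gap_60"]],
      persist90_any_ap = pers_a[["no_gap_90"]],
      ap_polypharmacy = poly_ap,
      psychiatric_polypharmacy = poly_psy,
      use_other_ap = cls_flag(ap_classes()),
      use_typical_oral = cls_flag("typical_oral_ap"),
      use_atypical_oral = cls_flag(oaa_classes()),
      use_typical_lai = cls_flag("typical_lai"),
      use_atypical_lai = cls_flag(c("pp1m", "other_atypical_lai")),
      use_anxiolytic = cls_flag("anxiolytic"),
      use_antidepressant = cls_flag("antidepressant"),
      use_mood_stabilizer = cls_flag("mood_stabilizer"),
      use_other_psych = cls_flag(psych_support_classes())
    )
  })
  dplyr::bind_rows(rows)
}

weighted_mean_sd <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  v <- sum(w * (x - m)^2) / W  # frequency-weight convention
  c(mean = m, sd = sqrt(v), n = W)
}

# Welch t-test treating normalized weights as frequencies.
weighted_ttest <- function(x1, w1, x2, w2) {
  a <- weighted_mean_sd(x1, w1); b <- weighted_mean_sd(x2, w2)
  se2 <- a[["sd"]]^2 / a[["n"]] + b[["sd"]]^2 / b[["n"]]
  if (se2 == 0) return(1)
  t <- (a[["mean"]] - b[["mean"]]) / sqrt(se2)
  df <- se2^2 / (a[["sd"]]^4 / (a[["n"]]^2 * (a[["n"]] - 1)) +
                   b[["sd"]]^4 / (b[["n"]]^2 * (b[["n"]] - 1)))
  2 * stats::pt(-abs(t), df)
}

# Pearson chi-square on the weighted 2x2 table.
weighted_chisq <- function(x1, w1, x2, w2) {
  o <- rbind(c(sum(w1 * x1), sum(w1 * !x1)), c(sum(w2 * x2), sum(w2 * !x2)))
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  if (any(e == 0)) return(1)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Weighted between-cohort comparison of treatment patterns
#'
#' Weighted means/proportions per cohort with two-sample p-values: Welch
#' t-test for continuous outcomes, Pearson chi-square for binary ones, both on
#' the weighted data.
#'
#' @param summaries Output of [exposure_summary()].
#' @param treated Logical vector (`TRUE` = treated cohort) aligned to rows.
#' @param weights Normalized weights aligned to rows (unit weights reproduce
#'   unweighted summaries).
#' @return A tibble with one row per outcome variable.
#' @export
summarize_patterns <- function(summaries, treated, weights = rep(1, nrow(summaries))) {
  stopifnot(nrow(summaries) == length(treated), length(treated) == length(weights))
  if (sum(weights[treated]) == 0 || sum(weights[!treated]) == 0) {
    rlang::abort("zero weight sum in a cohort", class = "claimsce_estimation_error")
  }
  vars <- setdiff(names(summaries), c("patient_id", "cohort"))
  rows <- lapply(vars, function(v) {
    x <- summaries[[v]]
    x1 <- x[treated]; w1 <- weights[treated]
    x2 <- x[!treated]; w2 <- weights[!treated]
    if (is.logical(x)) {
      tibble::tibble(variable = v, type = "binary",
                     treated_value = sum(w1 * x1) / sum(w1),
                     comparator_value = sum(w2 * x2) / sum(w2),
                     treated_sd = NA_real_, comparator_sd = NA_real_,
                     p_value = weighted_chisq(x1, w1, x2, w2))
    } else {
      a <- weighted_mean_sd(x1, w1); b <- weighted_mean_sd(x2, w2)
      tibble::tibble(variable = v, type = "continuous",
                     treated_value = a[["mean"]], comparator_value = b[["mean"]],
                     treated_sd = a[["sd"]], comparator_sd = b[["sd"]],
                     p_value = weighted_ttest(x1, w1, x2, w2))
    }
  })
  dplyr::bind_rows(rows)
}
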