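# Brute-force day-array oracles for the interval algebra, independent of the
# interval implementation: every statistic is recomputed on a 365-slot
# boolean array by direct enumeration.

WIN <- 365L

day_array <- function(dispense, days_supply) {
  covered <- rep(FALSE, WIN)
  for (i in seq_along(dispense)) {
    lo <- max(dispense[i] + 1L, 1L)              # day 0 -> slot 1
    hi <- min(dispense[i] + days_supply[i], WIN)
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  covered
}

oracle_pdc <- function(dispense, days_supply) sum(day_array(dispense, days_supply)) / WIN

# uncovered run lengths with a terminal marker, from the boolean array
oracle_runs <- function(covered) {
  r <- rle(covered)
  lens <- r$lengths[!r$values]
  if (length(lens) == 0) return(data.frame(length = integer(), terminal = logical()))
  terminal <- rep(FALSE, length(lens))
  if (!r$values[length(r$values)]) terminal[length(terminal)] <- TRUE
  data.frame(length = lens, terminal = terminal)
}

oracle_persistence <- function(dispense, days_supply, thresholds = c(30L, 60L, 90L),
                               count_terminal_gap = TRUE) {
  runs <- oracle_runs(day_array(dispense, days_supply))
  if (!count_terminal_gap) runs <- runs[!runs$terminal, , drop = FALSE]
  vapply(thresholds, function(g) !any(runs$length >= g), logical(1))
}

# exhaustive successor scan for the continuous-exposure chain
oracle_continuous_exposure <- function(dispense, days_supply, gap = 90L) {
  o <- order(dispense)
  d <- dispense[o]; s <- days_supply[o]
  keep <- d >= 0L & d <= WIN - 1L
  d <- d[keep]; s <- s[keep]
  if (length(d) == 0) return(0L)
  end <- d[1] + s[1] - 1L
  if (length(d) > 1) {
    for (i in 2:length(d)) {
      if (d[i] > end + gap) break
      end <- d[i] + s[i] - 1L
    }
  }
  min(end, WIN - 1L) + 1L
}

# bridge runs of uncovered days <= bridge that lie between covered days
oracle_bridge <- function(covered, bridge = 7L) {
  r <- rle(covered)
  n <- length(r$values)
  for (j in seq_len(n)) {
    if (!r$values[j] && j > 1 && j < n && r$lengths[j] <= bridge) r$values[j] <- TRUE
  }
  inverse.rle(r)
}

oracle_polypharmacy <- function(fill_list, classes, min_overlap = 60L,
                                bridge = 7L, mode = "ap_ap") {
  arrays <- lapply(fill_list, function(f) oracle_bridge(day_array(f$day, f$supply), bridge))
  agents <- names(fill_list)
  ap <- agents[classes[agents] %in% claimsce::ap_classes()]
  other <- agents[classes[agents] %in% claimsce::psych_support_classes()]
  pairs <- list()
  if (mode == "ap_ap") {
    if (length(ap) >= 2) pairs <- utils::combn(ap, 2, simplify = FALSE)
  } else {
    for (a in ap) for (b in other) pairs <- c(pairs, list(c(a, b)))
  }
  for (p in pairs) {
    both <- arrays[[p[1]]] & arrays[[p[2]]]
    r <- rle(both)
    if (any(r$values & r$lengths >= min_overlap)) return(TRUE)
  }
  FALSE
}

random_fills <- function(n_max = 50L) {
  n <- sample.int(n_max, 1)
  data.frame(day = sample(0:364, n, replace = TRUE),
             supply = sample(1:90, n, replace = TRUE))
}

# compact bundle builder for hand-made cohort scenarios (dates as offsets
# from 2010-06-01)
toy_bundle <- function(pharmacy_days, agents, patient_id = "T01",
                       birth = "1980-01-01", scz_days = c(-100L, -50L),
                       enroll = c(-400L, 400L), strict = TRUE,
                       supply = 30L) {
  origin <- as.Date("2010-06-01")
  patients <- tibble::tibble(patient_id = patient_id, birth_date = as.Date(birth),
                             sex = "male", race = "white", region = "urban",
                             state = "MO")
  enrollment <- tibble::tibble(patient_id = patient_id,
                               start_date = origin + enroll[1],
                               end_date = origin + enroll[2],
                               capitated = FALSE, dual_coverage = FALSE)
  map <- claimsce::default_agent_map()
  k <- match(agents, map$agent_code)
  pharmacy <- tibble::tibble(
    patient_id = patient_id, dispense_date = origin + pharmacy_days,
    agent_code = agents, agent_class = map$agent_class[k],
    days_supply = supply, paid_amount = 10, branded = map$branded[k],
    service_year = as.integer(format(origin + pharmacy_days, "%Y")))
  medical <- tibble::tibble(
    patient_id = patient_id, start_date = origin + scz_days,
    end_date = origin + scz_days, service_category = "outpatient",
    dx_codes = "295.30", paid_amount = 50, agent_code = "", branded = FALSE,
    service_year = as.integer(format(origin + scz_days, "%Y")))
  claimsce::claims_bundle(patients, enrollment, pharmacy, medical, strict = strict)
}
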