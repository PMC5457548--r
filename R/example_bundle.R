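#' Hand-built 12-patient example bundle
#'
#' A small synthetic bundle covering every cohort-selection outcome: clean
#' treated and comparator initiations (including a treated initiation visible
#' only through provider-administered medical claims), a second claim beyond
#' the 90-day limit, a washout violation, two different comparator agents
#' with no repeat, a missing second schizophrenia diagnosis, an under-18
#' initiator, broken pre-index enrollment, broken post-index enrollment, two
#' recently-diagnosed initiators, and a same-day tie between a treated and a
#' comparator candidate. The same bundle ships as delimited files under
#' `inst/extdata/bundle12/`.
#'
#' @return A strict `claims_bundle` of 12 patients.
#' @export
example_bundle <- function() {
  d <- as.Date
  patients <- tibble::tibble(
    patient_id = sprintf("EX%02d", 1:12),
    birth_date = d(c("1980-03-05", "1970-01-10", "1982-01-01", "1983-01-01",
                     "1985-06-15", "1992-08-01", "1980-01-01", "1975-05-05",
                     "1985-02-10", "1984-01-01", "1988-04-20", "1975-03-03")),
    sex = c("male", "female", "male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    race = c("white", "black", "white", "black", "white", "black", "white",
             "other", "white", "black", "white", "black"),
    region = c("urban", "rural", "urban", "suburban", "urban", "rural",
               "urban", "suburban", "urban", "rural", "suburban", "urban"),
    state = c("MO", "NJ", "IA", "KS", "MO", "MS", "MO", "NJ", "IA", "KS",
              "MO", "NJ")
  )
  enrollment <- tibble::tibble(
    patient_id = patients$patient_id,
    start_date = d(c(rep("2009-01-01", 6), "2010-01-01", "2009-01-01",
                     rep("2009-01-01", 4))),
    end_date = d(c(rep("2011-12-31", 7), "2010-09-15", rep("2011-12-31", 4))),
    capitated = rep(c(TRUE, FALSE), 6),
    dual_coverage = rep(c(FALSE, FALSE, TRUE), 4)
  )
  fill <- function(pid, dates, agent, supply = 30L, paid = 150) {
    map <- default_agent_map()
    k <- match(agent, map$agent_code)
    tibble::tibble(patient_id = pid, dispense_date = d(dates),
                   agent_code = agent, agent_class = map$agent_class[k],
                   days_supply = supply, paid_amount = paid,
                   branded = map$branded[k],
                   service_year = as.integer(substr(dates, 1, 4)))
  }
  pharmacy <- dplyr::bind_rows(
    # EX01: treated initiation with monthly refills + baseline psychiatric use
    fill("EX01", c("2010-06-01", "2010-07-01", "2010-08-01", "2010-09-01",
                   "2010-10-01", "2010-11-01", "2010-12-01"), "PP1M",
         paid = 1100),
    fill("EX01", "2009-12-01", "QUET"),
    fill("EX01", "2010-01-10", "LORA", paid = 20),
    fill("EX01", "2010-02-15", "CLON", paid = 20),
    # EX02: clean comparator initiation
    fill("EX02", c("2010-06-01", "2010-06-25", "2010-07-20", "2010-08-15"),
         "RISP"),
    # EX03: second claim 121 days after the first (beyond 90)
    fill("EX03", c("2010-06-01", "2010-09-30"), "QUET"),
    # EX04: washout violation (same agent 100 days before)
    fill("EX04", c("2010-02-21", "2010-06-01", "2010-06-20"), "OLAN"),
    # EX05: clean initiation but only one schizophrenia diagnosis date
    fill("EX05", c("2010-06-01", "2010-06-29"), "ARIP"),
    # EX06: age 17 at index
    fill("EX06", c("2010-06-01", "2010-06-22"), "RISP"),
    # EX07: enrollment starts 5 months before index
    fill("EX07", c("2010-06-01", "2010-06-26"), "QUET"),
    # EX08: enrollment ends 3.5 months after index
    fill("EX08", c("2010-06-01", "2010-06-25"), "OLAN"),
    # EX10: two different comparator agents, no repeat of either
    fill("EX10", "2010-06-01", "QUET"),
    fill("EX10", "2010-06-20", "OLAN"),
    # EX11: recently diagnosed comparator initiation
    fill("EX11", c("2010-06-01", "2010-07-15", "2010-08-20"), "LURA"),
    # EX12: same-day treated and comparator candidates (tie kept treated)
    fill("EX12", c("2010-06-01", "2010-06-28"), "PP1M", paid = 1100),
    fill("EX12", c("2010-06-01", "2010-06-21"), "RISP")
  )
  visit <- function(pid, dates, dx, category = "outpatient", paid = 120,
                    agent = "", los = 0L) {
    tibble::tibble(patient_id = pid, start_date = d(dates),
                   end_date = d(dates) + los, service_category = category,
                   dx_codes = dx, paid_amount = paid, agent_code = agent,
                   branded = agent == "PP1M",
                   service_year = as.integer(substr(dates, 1, 4)))
  }
  medical <- dplyr::bind_rows(
    visit("EX01", c("2010-01-15", "2010-03-10"), "295.30"),
    visit("EX02", c("2010-02-01", "2010-04-05"), "295.90;401.9"),
    visit("EX03", c("2010-01-20", "2010-02-20"), "295.30"),
    visit("EX04", c("2010-01-05", "2010-05-05"), "295.62"),
    visit("EX05", "2010-03-15", "295.30"),       # single schizophrenia date
    visit("EX05", "2010-04-10", "296.30"),
    visit("EX06", c("2010-01-11", "2010-02-11"), "295.30"),
    visit("EX07", c("2010-02-01", "2010-03-01"), "295.70"),
    visit("EX08", c("2010-01-09", "2010-02-09"), "295.30"),
    # EX09: treated initiation via provider-administered medical claims
    visit("EX09", c("2010-06-01", "2010-06-29"), "295.30", category = "other",
          paid = 1150, agent = "PP1M"),
    visit("EX09", c("2010-01-12", "2010-02-14"), "295.32"),
    visit("EX10", c("2010-01-03", "2010-02-03"), "295.30"),
    visit("EX11", c("2010-01-25", "2010-03-25"), "295.90"),
    visit("EX12", c("2010-01-18", "2010-02-18"), "295.30")
  )
  claims_bundle(patients, enrollment, pharmacy, medical, strict = TRUE)
}
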