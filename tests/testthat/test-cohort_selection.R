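test_that("index events follow the two-claims / washout rules on targeted fixtures", {
  # two treated claims 45 days apart, none before
  b <- toy_bundle(c(0L, 45L), c("PP1M", "PP1M"))
  ev <- find_index_events(b)
  expect_equal(ev$index_date, as.Date("2010-06-01"))
  expect_equal(ev$cohort, "PP1M")

  # second same-agent claim beyond 90 days: no event
  b2 <- toy_bundle(c(0L, 120L), c("QUET", "QUET"))
  expect_equal(nrow(find_index_events(b2)), 0)

  # washout violation: claims at -100, 0, 30
  b3 <- toy_bundle(c(-100L, 0L, 30L), c("OLAN", "OLAN", "OLAN"))
  expect_equal(nrow(find_index_events(b3)), 0)

  # same-day claims count as two qualifying claims
  b4 <- toy_bundle(c(0L, 0L), c("RISP", "RISP"))
  expect_equal(nrow(find_index_events(b4)), 1)

  # treated claims identifiable from medical claims only
  b5 <- toy_bundle(c(0L), c("OTHR"))
  md <- b5$medical
  origin <- as.Date("2010-06-01")
  md <- rbind(md, tibble::tibble(
    patient_id = "T01", start_date = origin + c(0L, 28L),
    end_date = origin + c(0L, 28L), service_category = "other",
    dx_codes = "295.30", paid_amount = 500, agent_code = "PP1M",
    branded = TRUE, service_year = 2010L))
  b5 <- claims_bundle(b5$patients, b5$enrollment, b5$pharmacy, md)
  ev5 <- find_index_events(b5)
  expect_equal(ev5$cohort, "PP1M")

  # an agent outside the eligible index classes never defines an event
  b6 <- toy_bundle(c(0L, 20L), c("HALO", "HALO"))
  expect_equal(nrow(find_index_events(b6)), 0)
})

test_that("index detection matches a brute-force scan on random bundles", {
  # independent oracle: evaluate the rule at every (agent, date) directly,
  # then apply the earliest-date / treated-first / alphabetical tie-break
  brute_index <- function(days, agents, accrual = 0L) {
    cand_date <- c(); cand_agent <- c()
    for (a in unique(agents)) {
      d <- sort(days[agents == a])
      for (D in unique(d[d >= accrual])) {
        if (any(d >= D - 365 & d <= D - 1)) next
        if (sum(d >= D & d <= D + 90) < 2) next
        cand_date <- c(cand_date, D); cand_agent <- c(cand_agent, a)
        break
      }
    }
    if (length(cand_date) == 0) return(NULL)
    best <- which(cand_date == min(cand_date))
    pp <- best[cand_agent[best] == "PP1M"]
    pick <- if (length(pp) > 0) pp[1] else best[order(cand_agent[best])][1]
    list(date = cand_date[pick], agent = cand_agent[pick])
  }
  set.seed(99)
  eligible <- c("PP1M", "ARIP", "OLAN", "QUET", "RISP")
  for (rep in 1:300) {
    n <- sample(2:8, 1)
    days <- sample(-400:200, n, replace = TRUE)
    agents <- sample(eligible, n, replace = TRUE)
    b <- toy_bundle(days, agents, enroll = c(-800L, 600L))
    ev <- find_index_events(b, accrual_start = as.Date("2010-06-01"))
    oracle <- brute_index(days, agents)
    if (is.null(oracle)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), 1)
      expect_equal(as.integer(ev$index_date - as.Date("2010-06-01")),
                   oracle$date)
      expect_equal(ev$index_agent, oracle$agent)
    }
  }
})

test_that("adding claims never deletes an index event and can only advance it", {
  base_days <- c(0L, 40L)
  b <- toy_bundle(base_days, c("QUET", "QUET"))
  d0 <- find_index_events(b)$index_date
  # an extra claim later in the window keeps the event
  b2 <- toy_bundle(c(base_days, 200L), rep("QUET", 3))
  expect_equal(find_index_events(b2)$index_date, d0)
  # an earlier pair (outside the washout reach of the old pair) moves it earlier
  b3 <- toy_bundle(c(-20L, 10L, 40L), rep("QUET", 3))
  expect_lt(find_index_events(b3)$index_date, d0)
})

test_that("inclusion flags localize the first failed criterion", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  got <- setNames(dec$exclusion_reason, dec$patient_id)
  expect_true(all(is.na(got[c("EX01", "EX02", "EX09", "EX11", "EX12")])))
  expect_equal(unname(got["EX05"]), "schizophrenia-dx")
  expect_equal(unname(got["EX06"]), "age-under-18")
  expect_equal(unname(got["EX07"]), "pre-enrollment")
  expect_equal(unname(got["EX08"]), "post-enrollment")
  expect_false(any(c("EX03", "EX04", "EX10") %in% dec$patient_id))

  # a short enrollment gap 100 days post-index breaks criterion e
  bgap <- toy_bundle(c(0L, 30L, 60L, 90L), rep("QUET", 4))
  en <- tibble::tibble(patient_id = "T01",
                       start_date = as.Date("2010-06-01") + c(-400L, 111L),
                       end_date = as.Date("2010-06-01") + c(100L, 500L),
                       capitated = FALSE, dual_coverage = FALSE)
  bgap <- claims_bundle(bgap$patients, en, bgap$pharmacy, bgap$medical)
  dgap <- apply_inclusion(bgap, find_index_events(bgap))
  expect_true(dgap$crit_d)
  expect_false(dgap$crit_e)
  expect_equal(dgap$exclusion_reason, "post-enrollment")
})

test_that("age and the recently-diagnosed band use completed years", {
  expect_equal(age_at(as.Date("1988-01-10"), as.Date("2010-06-01")), 22L)
  # 25 years and 364 days -> still 25, inside the band
  expect_equal(age_at(as.Date("1984-06-02"), as.Date("2010-06-01")), 25L)
  # 26th birthday on the index date -> outside
  expect_equal(age_at(as.Date("1984-06-01"), as.Date("2010-06-01")), 26L)

  b <- example_bundle()
  dec <- assign_subcohorts(apply_inclusion(b, find_index_events(b)), b$patients)
  rd <- setNames(dec$recently_diagnosed, dec$patient_id)
  expect_true(rd[["EX09"]])   # age 25 at index
  expect_true(rd[["EX11"]])   # age 22
  expect_false(rd[["EX01"]])  # age 30
})

test_that("baseline covariates are computed from pre-index claims only", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  cov <- build_baseline_covariates(b, dec[dec$included, ])
  ex01 <- cov[cov$patient_id == "EX01", ]
  # two distinct anxiolytic agents plus one antipsychotic in baseline
  expect_equal(ex01$n_unique_psych_agents, 3L)
  expect_true(ex01$ap_use)
  expect_true(ex01$ap_atypical_oral)
  expect_false(ex01$ap_typical_lai)
  # 30 covered antipsychotic days out of 365
  expect_equal(ex01$baseline_pdc, 30 / 365)
  expect_equal(ex01$baseline_pdc_cat, "pdc_lt80")
  expect_equal(ex01$quan_cci, 0L)
  expect_equal(ex01$index_year, 2010L)
  expect_equal(ex01$index_quarter, 2L)
  # baseline monthly medical cost: two 120-dollar 2010 visits, CPI-adjusted
  # to 2015 (446.752 / 388.436) and divided by 12
  expect_equal(ex01$baseline_monthly_medical, 240 * 446.752 / 388.436 / 12,
               tolerance = 1e-10)
  # index-date fills are excluded from the baseline window
  ex02 <- cov[cov$patient_id == "EX02", ]
  expect_equal(ex02$baseline_pdc_cat, "pdc_zero")
  expect_equal(ex02$n_unique_psych_agents, 0L)
  expect_false(ex02$ap_use)
})
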