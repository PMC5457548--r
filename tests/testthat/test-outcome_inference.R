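test_that("cost standardization is the CPI ratio and is linear", {
  cpi <- c(`2010` = 388.436, `2015` = 446.752)
  expect_equal(standardize_costs(100, 2015, cpi), 100)
  expect_equal(standardize_costs(100, 2010, cpi), 100 * 446.752 / 388.436)
  set.seed(1)
  a <- runif(50, 0, 1000); b <- runif(50, 0, 1000)
  yrs <- sample(c(2010, 2015), 50, replace = TRUE)
  expect_equal(standardize_costs(a + b, yrs, cpi),
               standardize_costs(a, yrs, cpi) + standardize_costs(b, yrs, cpi))
  expect_error(standardize_costs(1, 1999, cpi), class = "claimsce_config_error")
})

test_that("the branded discount applies only to branded claims", {
  expect_equal(apply_brand_discount(100, TRUE), 76.9)
  expect_equal(apply_brand_discount(100, FALSE), 100)
  set.seed(2)
  amt <- runif(30, 0, 500)
  expect_equal(sum(apply_brand_discount(amt, rep(TRUE, 30))),
               sum(amt) * (1 - 0.231))
  expect_error(apply_brand_discount(1, TRUE, rate = 1.2),
               class = "claimsce_config_error")
})

test_that("monthly costs aggregate standardized window claims by category", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  costs <- monthly_costs(b, dec[dec$included, ])
  ex09 <- costs[costs$patient_id == "EX09", ]
  # two provider-administered 1150-dollar claims in 2010, adjusted to 2015
  expect_equal(ex09$other_medical, 2300 * 446.752 / 388.436 / 12)
  expect_equal(ex09$pharmacy, 0)
  expect_equal(ex09$total, ex09$total_medical + ex09$pharmacy)
  ex01 <- costs[costs$patient_id == "EX01", ]
  # seven 1100-dollar treated fills in the window
  expect_equal(ex01$pharmacy, 7 * 1100 * 446.752 / 388.436 / 12)
  expect_equal(ex01$total_medical, 0)  # no follow-up medical claims
  # identities hold on synthetic data too
  gb <- simulate_bundle(120, seed = 4)
  dec2 <- apply_inclusion(gb$bundle, find_index_events(gb$bundle))
  c2 <- monthly_costs(gb$bundle, dec2[dec2$included, ])
  expect_equal(c2$total, c2$total_medical + c2$pharmacy)
  expect_equal(c2$total_medical,
               rowSums(c2[c("inpatient", "outpatient", "emergency_room",
                            "long_term_care", "mhi_admission", "mhi_1day",
                            "home_care", "other_medical")]))
})

test_that("utilization records count window events and stay days", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  util <- utilization_records(b, dec[dec$included, ])
  ex09 <- util[util$patient_id == "EX09", ]
  expect_equal(ex09$ev_other, 2L)
  expect_equal(ex09$ev_inpatient, 0L)
  expect_equal(ex09$person_years, 1)
})

test_that("the weighted OLS coefficient equals the weighted mean difference", {
  expect_equal(estimate_mmcd(c(10, 20, 10, 10), c(TRUE, TRUE, FALSE, FALSE)), 5)
  expect_equal(estimate_mmcd(rep(7, 10), rep(c(TRUE, FALSE), 5)), 0)
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    y <- rgamma(n, 2, 0.01)
    tr <- runif(n) < 0.4
    if (sum(tr) == 0 || sum(!tr) == 0) next
    w <- runif(n, 0.1, 3)
    direct <- sum(w[tr] * y[tr]) / sum(w[tr]) - sum(w[!tr] * y[!tr]) / sum(w[!tr])
    expect_equal(estimate_mmcd(y, tr, w), direct, tolerance = 1e-10)
  }
})

test_that("the weighted Poisson rate ratio equals the weighted rate ratio", {
  # treated: 10 events over 5 person-years; comparator: 4 over 4
  y <- c(3, 3, 2, 1, 1, 1, 1, 1, 1)
  tr <- c(rep(TRUE, 5), rep(FALSE, 4))
  expect_equal(estimate_rr(y, tr), 2, tolerance = 1e-8)
  expect_equal(estimate_rr(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1,
               tolerance = 1e-8)
  set.seed(4)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    y2 <- rpois(n, 2)
    tr2 <- runif(n) < 0.5
    w <- runif(n, 0.1, 3)
    if (sum(w[tr2] * y2[tr2]) == 0 || sum(w[!tr2] * y2[!tr2]) == 0) next
    direct <- (sum(w[tr2] * y2[tr2]) / sum(w[tr2])) /
      (sum(w[!tr2] * y2[!tr2]) / sum(w[!tr2]))
    expect_equal(estimate_rr(y2, tr2, w), direct, tolerance = 1e-8)
  }
  expect_error(estimate_rr(c(1, 0), c(TRUE, FALSE)),
               class = "claimsce_estimation_error")
})

test_that("bootstrap inference is deterministic and degenerates correctly", {
  set.seed(5)
  n <- 80
  covs <- tibble::tibble(x = rnorm(n))
  treated <- rep(c(TRUE, FALSE), n / 2)
  y <- rep(5, n)  # all costs identical
  est <- bootstrap_inference(y, treated, covs, "MMCD", B = 49, seed = 11,
                             ps_vars = "x")
  expect_equal(est$estimate, 0)
  expect_equal(est$ci_low, est$ci_high)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)

  y2 <- rnorm(n, 100, 10) + 20 * treated
  e1 <- bootstrap_inference(y2, treated, covs, "MMCD", B = 99, seed = 7,
                            ps_vars = "x")
  e2 <- bootstrap_inference(y2, treated, covs, "MMCD", B = 99, seed = 7,
                            ps_vars = "x")
  expect_identical(e1, e2)
  e3 <- bootstrap_inference(y2, treated, covs, "MMCD", B = 99, seed = 8,
                            ps_vars = "x")
  expect_false(identical(e1$ci_low, e3$ci_low))
})

test_that("the outcome suite covers every category and scenario", {
  gb <- simulate_bundle(250, seed = 9)
  dec <- apply_inclusion(gb$bundle, find_index_events(gb$bundle))
  cohort <- dec[dec$included, ]
  treated <- cohort$cohort == "PP1M"
  covs <- build_baseline_covariates(gb$bundle, cohort)
  costs <- monthly_costs(gb$bundle, cohort)
  util <- utilization_records(gb$bundle, cohort)
  disc <- monthly_costs(gb$bundle, cohort, discount = TRUE)
  eff <- run_outcome_suite(costs, util, covs, treated, discount_costs = disc,
                           B = 49, seed = 3)
  expect_equal(sum(eff$estimand == "MMCD" & eff$scenario == "main"), 11)
  expect_equal(sum(eff$estimand == "MMCD" & eff$scenario == "discount"), 2)
  expect_equal(sum(eff$estimand == "RR"), 8 + 3)
  expect_true(all(eff$seed == 3))
  ok <- !is.na(eff$estimate)
  expect_true(all(eff$ci_low[ok] <= eff$estimate[ok] + 1e-9))
  expect_true(all(eff$estimate[ok] <= eff$ci_high[ok] + 1e-9))

  # discount scenario is a no-op when no claim is branded
  generic <- costs
  disc2 <- monthly_costs(gb$bundle, cohort, discount = TRUE, discount_rate = 0)
  expect_equal(disc2, generic)
})
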