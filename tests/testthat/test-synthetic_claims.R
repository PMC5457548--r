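test_that("covariate generation is deterministic and hits configured margins", {
  cfg <- claims_sim_config(n_patients = 10000, seed = 7)
  g1 <- generate_covariates(cfg)
  g2 <- generate_covariates(cfg)
  expect_identical(g1$covariates, g2$covariates)
  expect_identical(g1$enrollment, g2$enrollment)
  # binomial concentration at n = 10^4
  expect_lt(abs(mean(g1$covariates$female) - 0.5), 0.02)
  expect_lt(abs(mean(g1$covariates$race == "white") - 0.5), 0.02)

  deg <- claims_sim_config(n_patients = 50, seed = 1,
                           race_probs = c(white = 1),
                           region_probs = c(rural = 1))
  gd <- generate_covariates(deg)
  expect_true(all(gd$covariates$race == "white"))
  expect_true(all(gd$covariates$region == "rural"))
})

test_that("invalid generator configurations are rejected", {
  expect_error(claims_sim_config(n_patients = 1), class = "claimsce_config_error")
  expect_error(claims_sim_config(p_female = 1.2), class = "claimsce_config_error")
  expect_error(claims_sim_config(cost_shape = 0), class = "claimsce_config_error")
  expect_error(claims_sim_config(nonsense = 1), class = "claimsce_config_error")
})

test_that("treatment assignment follows the logistic model", {
  cfg <- claims_sim_config(n_patients = 10000, seed = 3)
  covs <- generate_covariates(cfg)$covariates
  beta0 <- c(intercept = 0, age10 = 0, female = 0, prior_ap = 0, mhi = 0,
             drug_abuse = 0, como = 0)
  tr <- assign_treatment(covs, beta0, seed = 4)
  expect_true(all(tr$true_ps == 0.5))
  expect_lt(abs(mean(tr$treated) - 0.5), 0.02)
  # identical labels under the same seed
  expect_identical(tr$treated, assign_treatment(covs, beta0, seed = 4)$treated)

  # strong positive age coefficient: treated fraction rises across quintiles
  beta_age <- c(intercept = 0, age10 = 2, female = 0, prior_ap = 0, mhi = 0,
                drug_abuse = 0, como = 0)
  tr2 <- assign_treatment(covs, beta_age, seed = 5)
  q <- cut(covs$age, quantile(covs$age, 0:5 / 5), include.lowest = TRUE)
  frac <- tapply(tr2$treated, q, mean)
  expect_true(all(diff(frac) > 0))

  expect_error(assign_treatment(covs, c(1, 2), seed = 1),
               class = "claimsce_config_error")
})

test_that("fill generation controls the implied PDC", {
  cfg <- claims_sim_config()
  # continuous coverage: no extra gap, no discontinuation
  fc <- cfg$fill
  fc$gap_mean <- c(pp1m = 0, oaa = 0); fc$gap_dist <- "fixed"
  fc$p_discontinue <- c(pp1m = 0, oaa = 0)
  f <- generate_fills("pp1m", fc, seed = 1)
  expect_equal(nrow(f), 13)  # 13 monthly fills reach day 360
  expect_equal(compute_pdc(coverage_intervals(f$day, f$days_supply)), 1)

  # fixed 30-day extra gap: fill every 60 days, half coverage
  fc$gap_mean <- c(pp1m = 30, oaa = 30)
  f2 <- generate_fills("pp1m", fc, seed = 1)
  pdc <- oracle_pdc(f2$day, f2$days_supply)
  expect_equal(compute_pdc(coverage_intervals(f2$day, f2$days_supply)), pdc)
  expect_lt(abs(pdc - 0.5), 0.03)

  # first two fills are always within 90 days
  for (s in 1:25) {
    f3 <- generate_fills("oaa", cfg$fill, adherence_z = 1, seed = s)
    if (nrow(f3) >= 2) expect_lte(f3$day[2] - f3$day[1], 90)
  }
  expect_identical(generate_fills("oaa", cfg$fill, seed = 9),
                   generate_fills("oaa", cfg$fill, seed = 9))
})

test_that("outcome draws carry the configured effects", {
  cfg <- claims_sim_config(n_patients = 10000, seed = 11, delta_true = 0,
                           rr_true = 1)
  covs <- generate_covariates(cfg)$covariates
  treated <- rep(c(TRUE, FALSE), length.out = nrow(covs))
  out <- simulate_outcome_values(covs, treated, cfg, seed = 12)
  d <- mean(out$monthly_medical_cost[treated]) -
    mean(out$monthly_medical_cost[!treated])
  se <- sqrt(var(out$monthly_medical_cost[treated]) / sum(treated) +
               var(out$monthly_medical_cost[!treated]) / sum(!treated))
  expect_lt(abs(d), 3 * se)

  cfg2 <- claims_sim_config(n_patients = 10000, seed = 11, rr_true = 0.5)
  out2 <- simulate_outcome_values(covs, treated, cfg2, seed = 13)
  rr <- mean(out2$ev_outpatient[treated]) / mean(out2$ev_outpatient[!treated])
  expect_gt(rr, 0.45); expect_lt(rr, 0.55)

  cfg3 <- claims_sim_config(n_patients = 200, seed = 1, p_zero_cost = 1)
  out3 <- simulate_outcome_values(generate_covariates(cfg3)$covariates,
                                  rep(FALSE, 200), cfg3, seed = 1)
  expect_true(all(out3$monthly_medical_cost == 0))
})

test_that("generated bundles validate and pass the inclusion criteria", {
  gb <- simulate_bundle(500, seed = 1)
  expect_s3_class(gb$bundle, "claims_bundle")
  dec <- apply_inclusion(gb$bundle, find_index_events(gb$bundle))
  expect_gte(sum(dec$included) / 500, 0.90)
  # included cohorts match the generator's intended arms exactly
  m <- dplyr::inner_join(dec[dec$included, c("patient_id", "cohort")],
                         gb$truth[c("patient_id", "treated")],
                         by = "patient_id")
  expect_true(all((m$cohort == "PP1M") == m$treated))

  # reproducibility: identical bundles under the same config
  gb2 <- simulate_bundle(500, seed = 1)
  expect_identical(gb$bundle$pharmacy, gb2$bundle$pharmacy)
  expect_identical(gb$bundle$medical, gb2$bundle$medical)
  # different seeds differ but share the schema
  gb3 <- simulate_bundle(100, seed = 2)
  expect_false(identical(gb3$bundle$pharmacy, simulate_bundle(100, seed = 3)$bundle$pharmacy))
  expect_identical(names(gb3$bundle$pharmacy), names(gb$bundle$pharmacy))
})

test_that("a forced baseline enrollment gap excludes every patient at criterion d", {
  gb <- simulate_bundle(60, seed = 5, p_baseline_gap = 1)
  dec <- apply_inclusion(gb$bundle, find_index_events(gb$bundle))
  expect_true(all(!dec$crit_d))
  expect_equal(sum(dec$included), 0)
})

test_that("the injected cost effect equals delta_true within simulation error", {
  # Per repetition, subtract each patient's known covariate cost component
  # (true mean without the treatment term); the remaining arm difference of
  # realized costs is an oracle estimate of delta_true.
  reps <- 200
  delta <- -300
  d <- vapply(seq_len(reps), function(s) {
    smp <- simulate_analysis_sample(claims_sim_config(n_patients = 2000, seed = s))
    base <- smp$outcomes$true_mean_cost - delta * smp$treated
    resid <- smp$outcomes$monthly_medical_cost - base
    mean(resid[smp$treated]) - mean(resid[!smp$treated])
  }, numeric(1))
  se <- sd(d) / sqrt(reps)
  expect_lt(abs(mean(d) - delta), 3 * se + 1e-9)

  # confounding pushes the naive arm difference away from delta_true
  smp <- simulate_analysis_sample(claims_sim_config(n_patients = 20000, seed = 1))
  naive <- mean(smp$outcomes$monthly_medical_cost[smp$treated]) -
    mean(smp$outcomes$monthly_medical_cost[!smp$treated])
  expect_gt(naive, delta + 50)
})
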