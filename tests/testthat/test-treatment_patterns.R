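test_that("coverage calendars union overlapping and abutting supply", {
  # abutting 30-day fills form one interval of 60 covered days
  cal <- coverage_intervals(c(0L, 30L), c(30L, 30L))
  expect_equal(as.data.frame(cal), data.frame(start = 0L, end = 59L))
  # overlap collapses: fills at 0 and 15 cover 45 days
  cal2 <- coverage_intervals(c(0L, 15L), c(30L, 30L))
  expect_equal(as.data.frame(cal2), data.frame(start = 0L, end = 44L))
  expect_equal(compute_pdc(cal2), 45 / 365)
  # clipping to the window
  cal3 <- coverage_intervals(c(-10L, 350L), c(30L, 30L))
  expect_equal(sum(cal3$end - cal3$start + 1), 20 + 15)
})

test_that("interval statistics equal the day-array oracle on random fill sets", {
  set.seed(2024)
  for (rep in 1:300) {
    f <- random_fills()
    cal <- coverage_intervals(f$day, f$supply)
    expect_identical(compute_pdc(cal), oracle_pdc(f$day, f$supply))
    for (mode in c(TRUE, FALSE)) {
      expect_identical(
        unname(persistence_flags(cal, count_terminal_gap = mode)),
        unname(oracle_persistence(f$day, f$supply, count_terminal_gap = mode)))
    }
    ce <- continuous_exposure(f$day, f$supply)
    expect_identical(ce$duration, oracle_continuous_exposure(f$day, f$supply))
  }
})

test_that("continuous exposure walks the refill chain", {
  expect_equal(continuous_exposure(0L, 30L)$duration, 30L)
  # a 170-day gap breaks the chain after the first supply
  ce <- continuous_exposure(c(0L, 200L), c(30L, 30L))
  expect_equal(ce$duration, 30L)
  expect_equal(ce$n_dispensings, 2L)
  # gaps at exactly the permissible limit continue the chain
  expect_equal(continuous_exposure(c(0L, 119L), c(30L, 30L))$duration, 149L)
  expect_equal(continuous_exposure(c(0L, 120L), c(30L, 30L))$duration, 30L)
})

test_that("persistence flags respect thresholds and the terminal-gap mode", {
  full <- coverage_intervals(seq(0L, 360L, 30L), rep(30L, 13))
  expect_true(all(persistence_flags(full)))
  # single 70-day gap, terminal gap ignored
  cal <- coverage_intervals(c(0L, 100L), c(30L, 30L))
  flags <- persistence_flags(cal, count_terminal_gap = FALSE)
  expect_equal(unname(flags), c(FALSE, FALSE, TRUE))
  # counting the terminal gap (235 uncovered days at the end) fails all
  expect_equal(unname(persistence_flags(cal)), c(FALSE, FALSE, FALSE))
})

test_that("persistence at 30 implies 60 implies 90 on random inputs", {
  set.seed(7)
  for (rep in 1:200) {
    f <- random_fills()
    cal <- coverage_intervals(f$day, f$supply)
    for (mode in c(TRUE, FALSE)) {
      fl <- persistence_flags(cal, count_terminal_gap = mode)
      expect_true(!fl[["no_gap_30"]] || fl[["no_gap_60"]])
      expect_true(!fl[["no_gap_60"]] || fl[["no_gap_90"]])
    }
  }
})

test_that("PDC is monotone under adding fills", {
  set.seed(8)
  for (rep in 1:100) {
    f <- random_fills(20L)
    extra <- random_fills(5L)
    p1 <- compute_pdc(coverage_intervals(f$day, f$supply))
    p2 <- compute_pdc(coverage_intervals(c(f$day, extra$day),
                                         c(f$supply, extra$supply)))
    expect_gte(p2, p1)
  }
})

test_that("polypharmacy requires 60 overlapping days after 7-day bridging", {
  classes <- c(A = "quetiapine", B = "olanzapine", C = "anxiolytic")
  cal <- function(day, supply) coverage_intervals(day, supply)
  # A covers [0,100], B covers [20,90]: 71-day overlap
  cals <- list(A = cal(0L, 101L), B = cal(20L, 71L))
  expect_true(detect_polypharmacy(cals, classes, mode = "ap_ap"))
  # an 8-day hole in B splits the overlap into 31- and 32-day runs
  cals2 <- list(A = cal(0L, 101L), B = coverage_intervals(c(20L, 59L), c(31L, 32L)))
  expect_false(detect_polypharmacy(cals2, classes, mode = "ap_ap"))
  # a 7-day hole is bridged
  cals3 <- list(A = cal(0L, 101L), B = coverage_intervals(c(20L, 58L), c(31L, 33L)))
  expect_true(detect_polypharmacy(cals3, classes, mode = "ap_ap"))
  # one antipsychotic alone is never antipsychotic polypharmacy
  expect_false(detect_polypharmacy(list(A = cal(0L, 365L)), classes, mode = "ap_ap"))
  # antipsychotic + anxiolytic pairs only count in ap_other mode
  cals4 <- list(A = cal(0L, 80L), C = cal(10L, 80L))
  expect_false(detect_polypharmacy(cals4, classes, mode = "ap_ap"))
  expect_true(detect_polypharmacy(cals4, classes, mode = "ap_other"))
})

test_that("polypharmacy flags equal the day-array oracle on random calendars", {
  classes <- c(A = "pp1m", B = "risperidone", C = "typical_oral_ap",
               D = "anxiolytic", E = "mood_stabilizer")
  set.seed(31)
  for (rep in 1:150) {
    agents <- sample(names(classes), sample(2:4, 1))
    fills <- lapply(agents, function(a) random_fills(8L))
    names(fills) <- agents
    cals <- lapply(fills, function(f) coverage_intervals(f$day, f$supply))
    for (mode in c("ap_ap", "ap_other")) {
      expect_identical(
        detect_polypharmacy(cals, classes, mode = mode),
        oracle_polypharmacy(fills, classes, mode = mode),
        info = paste("mode", mode, "rep", rep))
    }
  }
})

test_that("polypharmacy is monotone under extending a calendar", {
  classes <- c(A = "quetiapine", B = "olanzapine")
  base <- list(A = coverage_intervals(0L, 70L), B = coverage_intervals(5L, 60L))
  expect_true(detect_polypharmacy(base, classes, mode = "ap_ap"))
  longer <- list(A = coverage_intervals(0L, 200L), B = base$B)
  expect_true(detect_polypharmacy(longer, classes, mode = "ap_ap"))
})

test_that("exposure summaries match hand-computed values on the fixture", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  pat <- exposure_summary(b, dec[dec$included, ])
  ex01 <- pat[pat$patient_id == "EX01", ]
  # seven first-of-month treated fills (days 0, 30, 61, 92, 122, 153, 183
  # with 30-day supply): 210 covered days, chain through day 212
  expect_equal(ex01$n_dispensings, 7L)
  expect_equal(ex01$duration_continuous_exposure, 213L)
  expect_equal(ex01$pdc_index, 210 / 365)
  expect_false(ex01$adherent_index)
  expect_false(ex01$persist30_index)  # terminal gap counts by default
  ex09 <- pat[pat$patient_id == "EX09", ]
  # provider-administered doses: two 30-day imputed supplies, days 0-28+29
  expect_equal(ex09$n_dispensings, 2L)
  expect_equal(ex09$pdc_index, 58 / 365)
})

test_that("weighted pattern comparison reduces to unweighted under unit weights", {
  b <- example_bundle()
  dec <- apply_inclusion(b, find_index_events(b))
  pat <- exposure_summary(b, dec[dec$included, ])
  treated <- pat$cohort == "PP1M"
  tab <- summarize_patterns(pat, treated)
  expect_equal(tab$treated_value[tab$variable == "pdc_index"],
               mean(pat$pdc_index[treated]))
  # identical cohorts: all p-values 1
  pat2 <- rbind(pat, pat)
  tr2 <- rep(c(TRUE, FALSE), each = nrow(pat))
  tab2 <- summarize_patterns(pat2, tr2)
  expect_true(all(tab2$p_value == 1))
  # weighted proportions equal the direct accumulation
  set.seed(5)
  w <- runif(nrow(pat2))
  tab3 <- summarize_patterns(pat2, tr2, w)
  v <- pat2$adherent_index
  expect_equal(tab3$treated_value[tab3$variable == "adherent_index"],
               sum(w[tr2] * v[tr2]) / sum(w[tr2]))
  expect_error(summarize_patterns(pat2, tr2, ifelse(tr2, 0, 1)),
               class = "claimsce_estimation_error")
})
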