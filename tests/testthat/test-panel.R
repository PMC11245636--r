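two_patient_cohort <- function() {
  co <- mk_cohort(list(A = c(500L, 90L), B = c(400L, 50L)),
                  rbind(trow("A", 10L, "haemoglobin", 14, "g/dL"),
                        trow("B", 20L, "haemoglobin", 14, "g/dL")))
  classify_cohort(co, default_catalog())
}

test_that("build_panel counts events and at-risk patients per month", {
  cc <- two_patient_cohort()
  pan <- build_panel(cc, request_events(cc, "FBC"), "requests_FBC")
  expect_identical(pan$at_risk, rep(2L, 24))   # both windows cover 730 days
  expect_identical(pan$events[pan$month == -1], 2L)
  expect_equal(pan$rate_per_1000[pan$month == -1], 1000)
  expect_identical(sum(pan$events), 2L)
})

test_that("a patient with a 300-day window is at risk for months -10..-1", {
  co <- mk_cohort(list(A = 300L, B = c(500L, 90L)))
  cc <- classify_cohort(co, default_catalog())
  pan <- build_panel(cc, request_events(cc, "FBC"))
  expect_identical(pan$at_risk[pan$month >= -10], rep(2L, 10))
  expect_identical(pan$at_risk[pan$month < -10], rep(1L, 14))
  # fixed-denominator variant uses the cohort size everywhere
  pan2 <- build_panel(cc, request_events(cc, "FBC"), denominator = "cohort")
  expect_identical(pan2$at_risk, rep(2L, 24))
})

test_that("panel events are conserved against the generator ledger", {
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 5))
  led <- attr(co, "ledger")
  cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
  pan <- build_panel(cc, request_events(cc, "FBC"))
  w <- cc$windows
  led <- led[led$patient_id %in% w$patient_id, ]
  led_in <- led[led$day_before <= w$start_day[match(led$patient_id, w$patient_id)], ]
  expect_identical(sum(pan$events), nrow(led_in))
  # and month by month
  by_month <- table(factor(led_in$month, levels = -24:-1))
  expect_identical(pan$events, as.integer(by_month))
})

test_that("panels add over disjoint cohorts", {
  co1 <- simulate_cohort(sim_config(n_patients = 40, seed = 31))
  co2 <- simulate_cohort(sim_config(n_patients = 40, seed = 32))
  co2$patients$patient_id <- paste0("Q", co2$patients$patient_id)
  co2$encounters$patient_id <- paste0("Q", co2$encounters$patient_id)
  co2$tests$patient_id <- paste0("Q", co2$tests$patient_id)
  union <- gp_cohort(rbind(co1$patients, co2$patients),
                     rbind(co1$encounters[, c("patient_id", "date")],
                           co2$encounters[, c("patient_id", "date")]),
                     rbind(co1$tests[, c("patient_id", "date", "analyte",
                                         "value", "unit")],
                           co2$tests[, c("patient_id", "date", "analyte",
                                         "value", "unit")]))
  p1 <- build_panel(classify_cohort(co1), request_events(classify_cohort(co1), "FBC"))
  p2 <- build_panel(classify_cohort(co2), request_events(classify_cohort(co2), "FBC"))
  cu <- classify_cohort(union)
  pu <- build_panel(cu, request_events(cu, "FBC"))
  expect_identical(pu$events, p1$events + p2$events)
  expect_identical(pu$at_risk, p1$at_risk + p2$at_risk)
})

test_that("tested proportions: incident is patient-level, cumulative nondecreasing", {
  # one patient tested every month
  days <- as.integer(30 * (0:23) + 15)
  spec <- do.call(rbind, lapply(days, function(d)
    trow("A", d, "haemoglobin", 14, "g/dL")))
  cc <- classify_cohort(mk_cohort(list(A = c(500L, 90L)), spec))
  pt <- proportion_tested(cc, "FBC")
  expect_equal(pt$incident_pct, rep(100, 24))
  expect_equal(pt$cumulative_pct, rep(100, 24))
  # nobody tested
  cc0 <- classify_cohort(mk_cohort(list(A = c(500L, 90L))))
  pt0 <- proportion_tested(cc0, "FBC")
  expect_equal(pt0$incident_pct, rep(0, 24))
  expect_equal(pt0$cumulative_pct, rep(0, 24))
  # two tests in one month count once
  cc2 <- classify_cohort(mk_cohort(list(A = c(500L, 90L)),
                                   rbind(trow("A", 70L, "haemoglobin", 14, "g/dL"),
                                         trow("A", 80L, "haemoglobin", 14, "g/dL"))))
  pt2 <- proportion_tested(cc2, "FBC")
  expect_equal(pt2$patients_tested[pt2$month == -3], 1L)
  expect_equal(pt2$incident_pct[pt2$month == -3], 100)
})

test_that("cumulative tested proportion is nondecreasing and bounded on random cohorts", {
  for (s in 1:5) {
    co <- simulate_cohort(sim_config(n_patients = 60, seed = 50 + s,
                                     test_request_prob_baseline = 0.1))
    cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
    pt <- proportion_tested(cc, "FBC")
    expect_true(all(diff(pt$cumulative_pct) >= 0))
    expect_true(all(pt$cumulative_pct <= 100))
    expect_true(all(pt$incident_pct >= 0 & pt$incident_pct <= 100, na.rm = TRUE))
  }
})

test_that("moving average truncates at the edges", {
  expect_equal(moving_average(c(1, 2, 3)), c(1.5, 2, 2.5))
  expect_equal(moving_average(rep(4, 10)), rep(4, 10))
  expect_equal(moving_average(c(5, 1, 7, 2), 1), c(5, 1, 7, 2))
  expect_equal(moving_average(1:5, 5), c(2, 2.5, 3, 3.5, 4))
  expect_error(moving_average(numeric(0)), "empty")
  expect_error(moving_average(1:3, 2))
})

test_that("inflammatory marker events OR-combine CRP and ESR per date", {
  cc <- classify_cohort(mk_cohort(
    list(A = c(500L, 90L)),
    rbind(trow("A", 100L, "crp", 60, "mg/L"),     # raised
          trow("A", 100L, "esr", 80, "mm/h"),     # raised, same day
          trow("A", 60L, "esr", 90, "mm/h"))))
  ev <- abnormal_events(cc, "inflammatory_marker")
  expect_identical(nrow(ev), 2L)  # one event per date, not per assay
  pan <- build_panel(cc, ev)
  expect_identical(sum(pan$events), 2L)
})
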