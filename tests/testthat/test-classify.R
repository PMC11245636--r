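cat12 <- default_catalog()

test_that("unit canonicalisation converts and is idempotent", {
  co <- mk_cohort(list(A = 100L),
                  rbind(trow("A", 50L, "haemoglobin", 115, "g/L"),
                        trow("A", 40L, "haemoglobin", 11.5, "g/dL"),
                        trow("A", 30L, "platelets", 250, "10^9/L")))
  out <- canonicalise_units(co$tests, cat12)
  expect_equal(out$value, c(11.5, 11.5, 250))
  expect_identical(out$unit, c("g/dL", "g/dL", "10^9/L"))
  expect_equal(canonicalise_units(out, cat12), out)  # idempotent
  bad <- co$tests
  bad$unit[1] <- "mmol/L"
  expect_error(canonicalise_units(bad, cat12), "haemoglobin.*mmol/L")
})

test_that("implausible values are excluded with a reason, never silently", {
  co <- mk_cohort(list(A = 100L),
                  rbind(trow("A", 50L, "haemoglobin", 0.2, "g/dL"),
                        trow("A", 40L, "haemoglobin", 14.0, "g/dL")))
  cat_hb <- cat12  # a laboratory-configured floor: haemoglobin below 3 g/dL
  cat_hb$analytes$plausible_min[cat_hb$analytes$assay == "haemoglobin"] <- 3
  flt <- filter_implausible(co$tests, cat_hb)
  expect_identical(nrow(flt$kept), 1L)
  expect_equal(flt$kept$value, 14.0)
  expect_identical(flt$rejected$reason, "below plausible_min")
  empty <- filter_implausible(co$tests[0, ], cat12)
  expect_identical(nrow(empty$kept), 0L)
  expect_identical(nrow(empty$rejected), 0L)
})

test_that("same-day repeats collapse to their mean, per assay", {
  co <- mk_cohort(list(A = 100L),
                  rbind(trow("A", 50L, "haemoglobin", 12.0, "g/dL"),
                        trow("A", 50L, "haemoglobin", 13.0, "g/dL"),
                        trow("A", 50L, "mcv", 90, "fL"),
                        trow("A", 20L, "haemoglobin", 11.0, "g/dL")))
  out <- dedup_same_day(co$tests)
  expect_identical(nrow(out), 3L)
  expect_equal(out$value[out$analyte == "haemoglobin" & out$days_before == 50L],
               12.5)
  # idempotent; exactly one row per (patient, date, assay)
  expect_equal(dedup_same_day(out), out)
  key <- paste(out$patient_id, out$date, out$analyte)
  expect_identical(anyDuplicated(key), 0L)
  single <- co$tests[3, ]
  expect_equal(dedup_same_day(single), single)
})

test_that("classification follows sex-specific bounds with normal boundaries", {
  co <- mk_cohort(list(A = 100L),
                  rbind(trow("A", 50L, "haemoglobin", 11.5, "g/dL"),
                        trow("A", 40L, "platelets", 450, "10^9/L"),
                        trow("A", 30L, "mcv", 90, "fL")))
  out <- classify_results(co$tests, co$patients, cat12)
  expect_identical(out$direction, c("low", "high", "normal"))
  expect_identical(out$of_interest, c(TRUE, TRUE, FALSE))
  # 11.5 is low for males (ref >= 13) but also low for females (ref >= 12);
  # 12.5 separates the sexes
  cof <- mk_cohort(list(A = 100L), trow("A", 50L, "haemoglobin", 12.5, "g/dL"),
                   sex = "female")
  expect_identical(classify_results(cof$tests, cof$patients, cat12)$direction,
                   "normal")
  com <- mk_cohort(list(A = 100L), trow("A", 50L, "haemoglobin", 12.5, "g/dL"),
                   sex = "male")
  expect_identical(classify_results(com$tests, com$patients, cat12)$direction,
                   "low")
})

test_that("boundary and near-boundary values classify deterministically for every assay and sex", {
  an <- cat12$analytes
  for (sex in c("male", "female")) {
    lo <- an[[paste0("lower_ref_", sex)]]
    hi <- an[[paste0("upper_ref_", sex)]]
    for (i in seq_len(nrow(an))) {
      eps <- (hi[i] - lo[i]) * 1e-6
      vals <- c(max(lo[i] - eps, eps), max(lo[i], eps), (lo[i] + hi[i]) / 2,
                hi[i], hi[i] + eps)
      spec <- do.call(rbind, lapply(seq_along(vals), function(j)
        trow("A", 10L + j, an$assay[i], vals[j], an$canonical_unit[i])))
      co <- mk_cohort(list(A = 100L), spec, sex = sex)
      out <- classify_results(co$tests, co$patients, cat12)
      expected <- c(if (lo[i] > 0) "low" else "normal",
                    "normal", "normal", "normal", "high")
      expect_identical(out$direction, expected,
                       label = paste(an$assay[i], sex))
    }
  }
})

test_that("classify_cohort chains the stages and windows the results", {
  co <- mk_cohort(list(A = c(500L, 90L), B = 200L),
                  rbind(trow("A", 600L, "haemoglobin", 115, "g/L"),
                        trow("A", 740L, "haemoglobin", 14, "g/dL"),
                        trow("B", 300L, "haemoglobin", 14, "g/dL"),
                        trow("B", 100L, "haemoglobin", 400, "g/dL")))
  cc <- classify_cohort(co, cat12)
  t <- cc$tests
  # A: window 730, day-600 result in window, converted and classified low
  a <- t[t$patient_id == "A" & t$days_before == 600L, ]
  expect_equal(a$value, 11.5)
  expect_identical(a$direction, "low")
  expect_true(a$in_window)
  # A: day-740 result beyond the 24-month frame
  expect_false(t$in_window[t$patient_id == "A" & t$days_before == 740L])
  # B: window starts day 200, so the day-300 result is out of window
  expect_false(t$in_window[t$patient_id == "B" & t$days_before == 300L])
  # B: implausible value rejected with reason
  expect_identical(nrow(cc$rejected), 1L)
})
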