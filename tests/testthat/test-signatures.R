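# cohort where every patient's abnormality history is written by hand;
# days are days before diagnosis, all within the 12-month window
precedence_cohort <- function(n_no_anaemia, n_other_first, n_anaemia_first) {
  ids <- sprintf("W%04d", seq_len(n_no_anaemia + n_other_first + n_anaemia_first))
  rows <- list()
  enc <- list()
  i <- 0
  for (k in seq_len(n_no_anaemia)) {        # raised RBCDW only, never anaemic
    i <- i + 1
    rows[[i]] <- trow(ids[i], 190L, "rbcdw", 18, "%")
    enc[[ids[i]]] <- c(500L, 90L)
  }
  for (k in seq_len(n_other_first)) {       # RBCDW at day 190, anaemia at 105
    i <- i + 1
    rows[[i]] <- rbind(trow(ids[i], 190L, "rbcdw", 18, "%"),
                       trow(ids[i], 105L, "haemoglobin", 10, "g/dL"))
    enc[[ids[i]]] <- c(500L, 90L)
  }
  for (k in seq_len(n_anaemia_first)) {     # anaemia only
    i <- i + 1
    rows[[i]] <- trow(ids[i], 105L, "haemoglobin", 10, "g/dL")
    enc[[ids[i]]] <- c(500L, 90L)
  }
  classify_cohort(mk_cohort(enc, do.call(rbind, rows)))
}

test_that("anaemia precedence categorises the canonical patient histories", {
  cc <- precedence_cohort(1, 1, 1)
  pr <- anaemia_precedence(cc)
  expect_identical(pr$n_with_abnormality, 3L)
  expect_identical(pr$n_no_anaemia, 1L)
  expect_identical(pr$n_other_first, 1L)
  expect_identical(pr$n_anaemia_first_or_tied, 1L)
})

test_that("the published precedence counts give 50.6%, printing as 51%", {
  cc <- precedence_cohort(103, 20, 120)   # 243 patients with an abnormality
  pr <- anaemia_precedence(cc)
  expect_identical(pr$n_with_abnormality, 243L)
  expect_equal(pr$percent_before_or_absent, 100 * 123 / 243, tolerance = 1e-12)
  expect_equal(round(pr$percent_before_or_absent, 1), 50.6)
  expect_identical(round(pr$percent_before_or_absent), 51)
})

test_that("same-day ties go to anaemia by default, flipped by the switch", {
  cc <- classify_cohort(mk_cohort(
    list(T1 = c(500L, 90L)),
    rbind(trow("T1", 100L, "rbcdw", 18, "%"),
          trow("T1", 100L, "haemoglobin", 10, "g/dL"))))
  expect_identical(anaemia_precedence(cc)$n_anaemia_first_or_tied, 1L)
  expect_identical(anaemia_precedence(cc, tie = "other_first")$n_other_first, 1L)
})

test_that("precedence categories partition patients with an abnormality", {
  for (s in 1:3) {
    co <- simulate_cohort(sim_config(n_patients = 120, seed = 60 + s,
                                     test_request_prob_baseline = 0.08))
    cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
    pr <- anaemia_precedence(cc)
    expect_identical(pr$n_no_anaemia + pr$n_other_first +
                       pr$n_anaemia_first_or_tied, pr$n_with_abnormality)
    # invariant to patient ordering
    perm <- co
    idx <- sample(nrow(perm$patients))
    perm$patients <- perm$patients[idx, ]
    cc2 <- suppressMessages(classify_cohort(eligible_cohort(perm)))
    expect_identical(anaemia_precedence(cc2)$percent_before_or_absent,
                     pr$percent_before_or_absent)
  }
})

test_that("tested/abnormal table uses cohort and tested denominators", {
  # 4 patients, 2 tested for haemoglobin, 1 abnormal
  cc <- classify_cohort(mk_cohort(
    list(A = c(500L, 90L), B = c(500L, 90L), C = c(500L, 90L), D = c(500L, 90L)),
    rbind(trow("A", 100L, "haemoglobin", 10, "g/dL"),
          trow("B", 100L, "haemoglobin", 14, "g/dL"))))
  tab <- tested_and_abnormal_table(cc)
  hb <- tab[tab$label == "low haemoglobin", ]
  expect_identical(hb$n_tested, 2L)
  expect_equal(hb$pct_tested, 50)
  expect_identical(hb$n_abnormal, 1L)
  expect_equal(hb$pct_abnormal, 50)
  # untested analytes are flagged with undefined abnormal percentage
  alb <- tab[tab$label == "low albumin", ]
  expect_true(alb$flagged)
  expect_true(is.na(alb$pct_abnormal))
  # ferritin appears once per direction of interest
  expect_identical(sum(tab$analyte == "ferritin"), 2L)
})

test_that("forcing every tested result abnormal gives 100% abnormal", {
  co <- simulate_cohort(sim_config(n_patients = 40, seed = 77,
                                   test_request_prob_baseline = 0.1,
                                   abnormality_prob_baseline = 1))
  cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
  tab <- tested_and_abnormal_table(cc)
  tested <- tab[tab$n_tested > 0 & tab$label %in% c("any_APR", "any_RBCI"), ]
  expect_true(all(tested$pct_abnormal == 100))
})

test_that("first-abnormality timing summarises the day set", {
  enc <- list(A = c(500L, 90L), B = c(500L, 90L), C = c(500L, 90L))
  cc <- classify_cohort(mk_cohort(
    enc,
    rbind(trow("A", 84L, "haemoglobin", 10, "g/dL"),
          trow("B", 27L, "haemoglobin", 10, "g/dL"),
          trow("C", 186L, "haemoglobin", 10, "g/dL"))))
  ts <- first_abnormal_timing(cc, "haemoglobin")
  expect_identical(ts$n, 3L)
  expect_equal(ts$median, 84)
  expect_equal(c(ts$min, ts$max), c(27, 186))
  expect_equal(ts$mean, mean(c(84, 27, 186)))
  expect_equal(ts$sd, sd(c(84, 27, 186)))
  # quantiles interpolate linearly between order statistics
  expect_equal(c(ts$q1, ts$q3),
               unname(quantile(c(84, 27, 186), c(0.25, 0.75))))
  # the first abnormality is the earliest in time: a later (smaller
  # days-before) repeat does not move it
  cc2 <- classify_cohort(mk_cohort(
    list(A = c(500L, 90L)),
    rbind(trow("A", 200L, "haemoglobin", 10, "g/dL"),
          trow("A", 50L, "haemoglobin", 10, "g/dL"))))
  expect_equal(first_abnormal_timing(cc2, "haemoglobin")$median, 200)
})

test_that("degenerate timing summaries are explicit", {
  cc <- classify_cohort(mk_cohort(list(A = c(500L, 90L)),
                                  trow("A", 10L, "haemoglobin", 10, "g/dL")))
  ts <- first_abnormal_timing(cc, "haemoglobin")
  expect_identical(ts$n, 1L)
  expect_equal(ts$sd, 0)
  expect_true(ts$sd_undefined)
  empty <- first_abnormal_timing(cc, "mcv")
  expect_identical(empty$n, 0L)
})

test_that("timing days stay within the signature window and patient windows", {
  co <- simulate_cohort(sim_config(n_patients = 120, seed = 91,
                                   test_request_prob_baseline = 0.08))
  cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
  for (sel in c("any_APR", "any_RBCI", "haemoglobin", "rbcdw")) {
    ts <- first_abnormal_timing(cc, sel)
    if (ts$n == 0) next
    expect_true(all(ts$days >= 0 & ts$days <= 365))
  }
  # n in the timing summary equals the abnormal count in the signature
  # table for single-direction analytes and the composites
  tab <- tested_and_abnormal_table(cc)
  for (lbl in c("any_APR", "any_RBCI", "low haemoglobin", "raised rbcdw")) {
    row <- tab[tab$label == lbl, ]
    sel <- if (grepl("^any", lbl)) lbl else row$analyte
    expect_identical(first_abnormal_timing(cc, sel)$n, row$n_abnormal,
                     label = lbl)
  }
})

test_that("timing comparison matches the closed-form Welch computation", {
  mk_timing_cohort <- function(ids, days, analyte = "haemoglobin") {
    enc <- setNames(rep(list(c(500L, 90L)), length(ids)), ids)
    spec <- do.call(rbind, lapply(seq_along(ids), function(i)
      trow(ids[i], days[i], analyte, 10, "g/dL")))
    classify_cohort(mk_cohort(enc, spec))
  }
  a_days <- c(30L, 80L, 120L, 200L, 310L)
  b_days <- c(10L, 90L, 140L, 260L)
  ca <- mk_timing_cohort(paste0("A", 1:5), a_days)
  cb <- mk_timing_cohort(paste0("B", 1:4), b_days)
  out <- compare_timing(ca, cb, "haemoglobin")
  # closed-form Welch statistic and Welch-Satterthwaite df
  va <- var(a_days) / 5
  vb <- var(b_days) / 4
  t_ref <- (mean(a_days) - mean(b_days)) / sqrt(va + vb)
  df_ref <- (va + vb)^2 / (va^2 / 4 + vb^2 / 3)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(out$t, t_ref, tolerance = 1e-10)
  expect_equal(out$df, df_ref, tolerance = 1e-10)
  expect_equal(out$p_value, p_ref, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- compare_timing(mk_timing_cohort(paste0("C", 1:3), c(30L, 60L, 90L)),
                         mk_timing_cohort(paste0("D", 1:3), c(30L, 60L, 90L)),
                         "haemoglobin")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # clearly separated samples
  sep <- compare_timing(mk_timing_cohort(paste0("E", 1:3), c(1L, 2L, 3L)),
                        mk_timing_cohort(paste0("F", 1:3), c(101L, 102L, 103L)),
                        "haemoglobin")
  expect_lt(sep$p_value, 0.001)
  # undefined below two patients per group
  expect_warning(
    und <- compare_timing(mk_timing_cohort("G1", 10L),
                          mk_timing_cohort(paste0("H", 1:3), c(30L, 60L, 90L)),
                          "haemoglobin"),
    "undefined")
  expect_true(is.na(und$p_value))
})
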