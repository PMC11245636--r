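#!/usr/bin/env Rscript
# Trends in blood-test *requests* before diagnosis.
#
# For each cohort: monthly FBC/APR request-rate panels over the 24 months
# before diagnosis, the inflexion month at which requests first depart from
# the background rate (sequential hinge Poisson models), rate ratios
# against the month -24 baseline, and incident/cumulative tested
# proportions. Run analysis/01_simulate_cohorts.R first.

suppressPackageStartupMessages(library(prediagblood))

for (label in c("crc", "lc")) {
  co <- read_cohort(file.path("results/cohorts", label, "patients.csv"),
                    file.path("results/cohorts", label, "encounters.csv"),
                    file.path("results/cohorts", label, "tests.csv"))
  cc <- classify_cohort(eligible_cohort(co))
  out <- file.path("results/testing_trends", label)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cat("\n==", toupper(label), "cohort:", nrow(cc$patients), "patients ==\n")
  for (grp in c("FBC", "APR")) {
    pan <- build_panel(cc, request_events(cc, grp), paste0("requests_", grp))
    pan$smoothed_rate <- moving_average(pan$rate_per_1000, 3)
    write.csv(pan, file.path(out, paste0("panel_requests_", grp, ".csv")),
              row.names = FALSE)
    fit <- fit_changepoint(pan)
    cat(grp, "requests: inflexion", fit$k_star, "months before diagnosis",
        sprintf("(LRT p = %.3g%s)", fit$p_value,
                if (fit$no_inflexion) "; not distinguishable from flat" else ""),
        "\n")
    rr <- rate_ratios(pan)
    write.csv(rr, file.path(out, paste0("rate_ratios_", grp, ".csv")),
              row.names = FALSE)
    cat("  rate in month -1 vs -24:",
        sprintf("RR %.2f (fold increase %.1f on smoothed rates)\n",
                rr$rr[rr$month == -1], fold_increase(pan)))
    write.csv(proportion_tested(cc, grp),
              file.path(out, paste0("proportion_tested_", grp, ".csv")),
              row.names = FALSE)
  }
}
cat("\ntables written under results/testing_trends/\n")
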