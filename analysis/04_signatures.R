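#!/usr/bin/env Rscript
# Cancer-type abnormality signatures in the year before diagnosis.
#
# Produces, for both cohorts: the tested/abnormal proportion table, the
# anaemia-precedence categorisation (how often another abnormality appears
# before, or without, anaemia), first-abnormality timing summaries, and the
# Welch t-test comparison of timing between the colorectal and lung
# cohorts. A sensitivity run repeats the CRC signature table excluding
# screen-detected patients.

suppressPackageStartupMessages(library(prediagblood))

load_cc <- function(label, exclude_screen = FALSE) {
  co <- read_cohort(file.path("results/cohorts", label, "patients.csv"),
                    file.path("results/cohorts", label, "encounters.csv"),
                    file.path("results/cohorts", label, "tests.csv"))
  co <- filter_screen_detected(eligible_cohort(co), exclude_screen)
  classify_cohort(co)
}
crc <- load_cc("crc")
lc <- load_cc("lc")
out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (pair in list(list("crc", crc), list("lc", lc))) {
  label <- pair[[1]]; cc <- pair[[2]]
  write.csv(tested_and_abnormal_table(cc),
            file.path(out, paste0("signature_table_", label, ".csv")),
            row.names = FALSE)
  pr <- anaemia_precedence(cc)
  jsonlite::write_json(unclass(pr),
                       file.path(out, paste0("precedence_", label, ".json")),
                       auto_unbox = TRUE, digits = NA)
  cat("\n==", toupper(label), "==\n")
  print(pr)
}

# sensitivity: CRC signature excluding screen-detected patients
write.csv(tested_and_abnormal_table(load_cc("crc", exclude_screen = TRUE)),
          file.path(out, "signature_table_crc_no_screen.csv"),
          row.names = FALSE)

# timing of the first abnormal result, both cohorts side by side
selectors <- c("any_APR", "any_RBCI", unique(crc$catalog$analytes$analyte))
timing <- do.call(rbind, lapply(selectors, function(sel) {
  a <- first_abnormal_timing(crc, sel)
  b <- first_abnormal_timing(lc, sel)
  cmp <- suppressWarnings(compare_timing(crc, lc, sel))
  data.frame(selector = sel,
             crc_n = a$n,
             crc_median = if (a$n) a$median else NA,
             crc_mean = if (a$n) a$mean else NA,
             lc_n = b$n,
             lc_median = if (b$n) b$median else NA,
             lc_mean = if (b$n) b$mean else NA,
             t = cmp$t, p_value = cmp$p_value)
}))
write.csv(timing, file.path(out, "timing.csv"), row.names = FALSE)
cat("\nEarliest-detected abnormalities (median days before diagnosis):\n")
print(head(timing[order(-timing$crc_median), c("selector", "crc_median",
                                               "lc_median", "p_value")], 5),
      row.names = FALSE)
cat("\ntables written under results/signatures/\n")
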