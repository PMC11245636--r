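#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts.
#
# The linked registry/EHR data behind the real analysis are not publicly
# available, so the workflow runs on seeded synthetic cohorts that carry the
# structure the analysis assumes: a colorectal-scale cohort (855 patients,
# baseline FBC-request probability 0.02/month growing 1.22-fold per month
# after month -7) and a lung-scale cohort (399 patients, 0.03 baseline,
# 1.20-fold growth after month -6). Both are written in the three-CSV
# interchange format under results/cohorts/.

suppressPackageStartupMessages(library(prediagblood))

crc <- simulate_cohort(sim_config(seed = 20260920L))
lc <- simulate_cohort(lc_config(seed = 20260921L))

write_cohort(crc, "results/cohorts/crc")
write_cohort(lc, "results/cohorts/lc")

cat("CRC cohort:", nrow(crc$patients), "patients,",
    nrow(crc$tests), "test results;",
    sum(crc$patients$screen_detected), "screen-detected\n")
cat("LC cohort: ", nrow(lc$patients), "patients,",
    nrow(lc$tests), "test results\n")
cat("written to results/cohorts/{crc,lc}\n")
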