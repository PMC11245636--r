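# fixture builders: small cohorts specified by days-before-diagnosis

DX <- as.Date("2020-06-01")

mk_patients <- function(ids, sex = "male", cancer_type = "CRC",
                        birth_year = 1955L, screen_detected = FALSE,
                        diagnosis_date = DX) {
  data.frame(patient_id = ids, cancer_type = cancer_type,
             diagnosis_date = diagnosis_date, sex = sex,
             birth_year = birth_year, screen_detected = screen_detected,
             stringsAsFactors = FALSE)
}

# encounter_days: named list patient_id -> integer days before diagnosis
mk_encounters <- function(encounter_days, diagnosis_date = DX) {
  if (!length(encounter_days))
    return(data.frame(patient_id = character(), date = as.Date(character())))
  data.frame(patient_id = rep(names(encounter_days), lengths(encounter_days)),
             date = diagnosis_date - unlist(encounter_days, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# tests_spec: data.frame(patient_id, day, analyte, value, unit)
mk_tests <- function(tests_spec = NULL, diagnosis_date = DX) {
  if (is.null(tests_spec) || !nrow(tests_spec))
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      analyte = character(), value = numeric(),
                      unit = character(), stringsAsFactors = FALSE))
  data.frame(patient_id = tests_spec$patient_id,
             date = diagnosis_date - tests_spec$day,
             analyte = tests_spec$analyte, value = tests_spec$value,
             unit = tests_spec$unit, stringsAsFactors = FALSE)
}

mk_cohort <- function(encounter_days, tests_spec = NULL, sex = "male", ...) {
  ids <- names(encounter_days)
  gp_cohort(mk_patients(ids, sex = sex, ...),
            mk_encounters(encounter_days),
            mk_tests(tests_spec))
}

# a row of the tests_spec table
trow <- function(patient_id, day, analyte, value, unit) {
  data.frame(patient_id = patient_id, day = day, analyte = analyte,
             value = value, unit = unit, stringsAsFactors = FALSE)
}

# constructed monthly panel with exact counts
mk_panel <- function(events, at_risk = 1000L, months = -24:-1) {
  structure(data.frame(month = months, at_risk = at_risk,
                       events = as.integer(events),
                       rate_per_1000 = 1000 * events / at_risk),
            class = c("monthly_panel", "data.frame"))
}
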