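#' Convert test results to canonical units
#'
#' Laboratories report the same assay in different units (e.g. haemoglobin
#' in g/L or g/dL); each value is rescaled to the catalogue's canonical unit
#' by its conversion factor (haemoglobin g/L divides by 10). Applying the
#' conversion twice is the same as applying it once.
#'
#' @param tests test-result data frame (columns \code{analyte}, \code{value},
#'   \code{unit}, ...), as in \code{\link{gp_cohort}}.
#' @param catalog an \code{\link{default_catalog}}-style catalogue.
#' @return \code{tests} with \code{value} in canonical units and \code{unit}
#'   updated.
#' @export
canonicalise_units <- function(tests, catalog) {
  if (!nrow(tests)) return(tests)
  bad <- !tests$analyte %in% catalog$analytes$assay
  if (any(bad))
    stop("unknown assay code(s): ", paste(unique(tests$analyte[bad]), collapse = ", "))
  key <- paste(tests$analyte, tests$unit, sep = "\r")
  ukey <- paste(catalog$units$assay, catalog$units$unit, sep = "\r")
  idx <- match(key, ukey)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop("unknown unit for assay ", tests$analyte[i], ": '", tests$unit[i], "'")
  }
  tests$value <- tests$value * catalog$units$factor[idx]
  tests$unit <- catalog$analytes$canonical_unit[match(tests$analyte, catalog$analytes$assay)]
  tests
}

#' Exclude biologically implausible results
#'
#' Values outside the catalogue's plausibility bounds (far beyond any
#' physiological range, usually unit or transcription errors) are removed
#' from analysis but never silently: the rejected rows are returned with a
#' reason.
#'
#' @param tests canonicalised test-result data frame.
#' @param catalog analyte catalogue.
#' @return list with elements \code{kept} and \code{rejected} (the latter
#'   with a \code{reason} column).
#' @export
filter_implausible <- function(tests, catalog) {
  if (!nrow(tests)) {
    tests$reason <- character(0)
    return(list(kept = tests[, setdiff(names(tests), "reason")], rejected = tests))
  }
  i <- match(tests$analyte, catalog$analytes$assay)
  lo <- catalog$analytes$plausible_min[i]
  hi <- catalog$analytes$plausible_max[i]
  ok <- tests$value >= lo & tests$value <= hi
  rejected <- tests[!ok, , drop = FALSE]
  rejected$reason <- ifelse(rejected$value < lo[!ok],
                            "below plausible_min", "above plausible_max")
  rownames(rejected) <- NULL
  kept <- tests[ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Collapse same-day repeat results to their mean
#'
#' When a patient has several results for the same assay on the same day,
#' one record with the arithmetic mean value is kept, preventing duplicate
#' counting. Idempotent; records of different assays on one day are all
#' kept (CRP and ESR are distinct assays and are never averaged together).
#'
#' @param tests canonicalised test-result data frame.
#' @return deduplicated data frame, at most one row per
#'   (patient, date, assay).
#' @export
dedup_same_day <- function(tests) {
  if (!nrow(tests)) return(tests)
  key <- paste(tests$patient_id, as.character(tests$date), tests$analyte, sep = "\r")
  if (!anyDuplicated(key)) return(tests)
  mv <- tapply(tests$value, key, mean)
  out <- tests[!duplicated(key), , drop = FALSE]
  out$value <- as.numeric(mv[paste(out$patient_id, as.character(out$date),
                                   out$analyte, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Classify results against sex-specific reference ranges
#'
#' Each (canonicalised, plausible) result is classified as \code{"low"}
#' (below the sex-specific lower reference bound), \code{"high"} (above the
#' upper bound) or \code{"normal"}; values exactly on a bound are normal.
#' A result is an abnormality of interest when its direction is one the
#' analyte's clinical signature uses (e.g. low haemoglobin = anaemia, high
#' platelets = thrombocytosis; ferritin is of interest in both directions).
#'
#' @param tests test-result data frame.
#' @param patients patient table supplying \code{sex} by \code{patient_id}.
#' @param catalog analyte catalogue.
#' @return \code{tests} with columns added: \code{analyte_logical} (CRP and
#'   ESR collapse to \code{inflammatory_marker}), \code{group}
#'   (\code{"APR"}/\code{"RBCI"}), \code{direction} and \code{of_interest}.
#' @export
classify_results <- function(tests, patients, catalog) {
  an <- catalog$analytes
  i <- match(tests$analyte, an$assay)
  if (anyNA(i))
    stop("unknown assay code(s): ",
         paste(unique(tests$analyte[is.na(i)]), collapse = ", "))
  sex <- patients$sex[match(tests$patient_id, patients$patient_id)]
  lo <- ifelse(sex == "male", an$lower_ref_male[i], an$lower_ref_female[i])
  hi <- ifelse(sex == "male", an$upper_ref_male[i], an$upper_ref_female[i])
  direction <- rep("normal", nrow(tests))
  direction[tests$value < lo] <- "low"
  direction[tests$value > hi] <- "high"
  tests$analyte_logical <- an$analyte[i]
  tests$group <- an$group[i]
  tests$direction <- direction
  tests$of_interest <- (direction == "low" & an$low_of_interest[i]) |
    (direction == "high" & an$high_of_interest[i])
  tests
}

#' Run the full result-preparation chain on a cohort
#'
#' Applies, in order: unit canonicalisation, plausibility filtering,
#' same-day deduplication (per assay), classification against sex-specific
#' reference ranges, and observation windowing. This prepared form is the
#' input to the panel and signature analyses.
#'
#' @param cohort an eligible \code{\link{gp_cohort}}.
#' @param catalog analyte catalogue; defaults to \code{\link{default_catalog}()}.
#' @return An object of class \code{classified_cohort}: the cohort list plus
#'   \item{windows}{per-patient observation windows
#'     (\code{\link{observation_window}}).}
#'   \item{tests}{the prepared result table with classification columns,
#'     \code{month} (\code{\link{month_index}}) and \code{in_window}
#'     (within the patient's observation window and the 24-month frame).}
#'   \item{rejected}{implausible rows, with reasons.}
#' @export
classify_cohort <- function(cohort, catalog = default_catalog()) {
  win <- observation_window(cohort)
  tests <- canonicalise_units(cohort$tests, catalog)
  flt <- filter_implausible(tests, catalog)
  tests <- dedup_same_day(flt$kept)
  tests <- classify_results(tests, cohort$patients, catalog)
  tests$month <- month_index(tests$days_before)
  start <- win$start_day[match(tests$patient_id, win$patient_id)]
  tests$in_window <- !is.na(tests$month) & tests$days_before <= start &
    tests$days_before >= 1
  out <- cohort
  out$tests <- tests
  out$windows <- win
  out$rejected <- flt$rejected
  out$catalog <- catalog
  class(out) <- c("classified_cohort", "gp_cohort")
  out
}
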