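#' Construct a linked GP cohort
#'
#' A cohort bundles the three linked tables of the analysis: one row per
#' cancer patient, their GP encounter dates, and their blood-test results.
#' All downstream functions (\code{\link{classify_results}},
#' \code{\link{build_panel}}, \code{\link{anaemia_precedence}}, ...) operate
#' on this container.
#'
#' @param patients data frame with columns \code{patient_id},
#'   \code{cancer_type} (\code{"CRC"} or \code{"LC"}), \code{diagnosis_date}
#'   (\code{Date} or ISO-8601 string), \code{sex} (\code{"male"}/\code{"female"}),
#'   \code{birth_year}, \code{screen_detected} (logical or 0/1).
#' @param encounters data frame with columns \code{patient_id}, \code{date}.
#' @param tests data frame with columns \code{patient_id}, \code{date},
#'   \code{analyte} (assay code as in the catalogue), \code{value},
#'   \code{unit}.
#' @return An object of class \code{gp_cohort}: a list with elements
#'   \code{patients}, \code{encounters} and \code{tests}, with dates parsed
#'   and a \code{days_before} column (integer days strictly before diagnosis)
#'   added to the encounter and test tables. Encounter or test rows whose
#'   \code{patient_id} is absent from \code{patients} are dropped; their
#'   count is kept in \code{attr(, "n_rejected")} and reported via a message.
#' @export
gp_cohort <- function(patients, encounters, tests) {
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("missing required column(s) in ", what, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    df
  }
  patients <- req(patients, c("patient_id", "cancer_type", "diagnosis_date",
                              "sex", "birth_year", "screen_detected"), "patients")
  encounters <- req(encounters, c("patient_id", "date"), "encounters")
  tests <- req(tests, c("patient_id", "date", "analyte", "value", "unit"), "tests")

  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table")
  patients$diagnosis_date <- parse_iso_date(patients$diagnosis_date, "patients")
  patients$screen_detected <- as.logical(as.integer(patients$screen_detected))
  stopifnot(all(patients$cancer_type %in% c("CRC", "LC")),
            all(patients$sex %in% c("male", "female")))

  encounters$patient_id <- as.character(encounters$patient_id)
  tests$patient_id <- as.character(tests$patient_id)
  encounters$date <- parse_iso_date(encounters$date, "encounters")
  tests$date <- parse_iso_date(tests$date, "tests")
  if (nrow(tests) && any(!is.finite(tests$value) | tests$value <= 0))
    stop("test values must be finite and positive")

  known <- patients$patient_id
  n_rej <- sum(!encounters$patient_id %in% known) + sum(!tests$patient_id %in% known)
  if (n_rej > 0)
    message("gp_cohort: rejected ", n_rej, " row(s) referencing unknown patients")
  encounters <- encounters[encounters$patient_id %in% known, , drop = FALSE]
  tests <- tests[tests$patient_id %in% known, , drop = FALSE]

  dx <- patients$diagnosis_date[match(encounters$patient_id, known)]
  encounters$days_before <- as.integer(dx - encounters$date)
  dx <- patients$diagnosis_date[match(tests$patient_id, known)]
  tests$days_before <- as.integer(dx - tests$date)
  if ((nrow(encounters) && any(encounters$days_before < 0)) ||
      (nrow(tests) && any(tests$days_before < 0)))
    stop("encounter/test dates after diagnosis are not allowed")

  rownames(patients) <- rownames(encounters) <- rownames(tests) <- NULL
  structure(list(patients = patients, encounters = encounters, tests = tests),
            n_rejected = n_rej, class = "gp_cohort")
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d) && length(bad <- which(is.na(d))))
    stop("unparsable date in ", what, " at row ", bad[1], ": ",
         as.character(x)[bad[1]], call. = FALSE)
  d
}

#' @export
print.gp_cohort <- function(x, ...) {
  cat("<gp_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$encounters), " encounters, ", nrow(x$tests), " test results\n",
      sep = "")
  invisible(x)
}

#' Read a cohort from its three CSV files
#'
#' Reads the flat-file interchange format (\code{patients.csv},
#' \code{encounters.csv}, \code{tests.csv}; UTF-8, ISO-8601 dates) produced
#' by \code{\link{write_cohort}} or exported from a linked EHR extract.
#'
#' @param patients_path,encounters_path,tests_path CSV file paths.
#' @return a \code{\link{gp_cohort}}.
#' @export
read_cohort <- function(patients_path, encounters_path, tests_path) {
  for (p in c(patients_path, encounters_path, tests_path))
    if (!file.exists(p)) stop("file not found: ", p)
  gp_cohort(utils::read.csv(patients_path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character")),
            utils::read.csv(encounters_path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character")),
            utils::read.csv(tests_path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character")))
}

#' Eligibility: adult with a GP encounter in the year before diagnosis
#'
#' A patient enters the analysis if aged 18 or more at diagnosis and with at
#' least one GP encounter in the 365 days before diagnosis (day 365
#' inclusive; the diagnosis day itself, day 0, does not count as
#' pre-diagnostic).
#'
#' @param cohort a \code{gp_cohort}.
#' @return named logical vector, one element per patient.
#' @export
is_eligible <- function(cohort) {
  p <- cohort$patients
  age <- as.integer(format(p$diagnosis_date, "%Y")) - p$birth_year
  e <- cohort$encounters
  recent <- unique(e$patient_id[e$days_before >= 1 & e$days_before <= 365])
  out <- age >= 18 & p$patient_id %in% recent
  names(out) <- p$patient_id
  out
}

#' Restrict a cohort to eligible patients
#'
#' @param cohort a \code{gp_cohort}.
#' @return the cohort with ineligible patients (and their encounters/tests)
#'   removed; the number dropped is reported via a message.
#' @export
eligible_cohort <- function(cohort) {
  keep <- is_eligible(cohort)
  if (any(!keep))
    message("eligible_cohort: dropped ", sum(!keep), " ineligible patient(s)")
  subset_cohort(cohort, names(keep)[keep])
}

subset_cohort <- function(cohort, ids) {
  structure(list(
    patients = cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE],
    encounters = cohort$encounters[cohort$encounters$patient_id %in% ids, , drop = FALSE],
    tests = cohort$tests[cohort$tests$patient_id %in% ids, , drop = FALSE]),
    class = "gp_cohort")
}

#' Observation window for pre-diagnostic data extraction
#'
#' Data are considered observable for the full 24 months (730 days) before
#' diagnosis when the patient attended their GP in both pre-diagnosis years
#' (at least one encounter in days 366--730 and one in days 1--365);
#' otherwise the window opens at the patient's first GP encounter within 730
#' days of diagnosis. The window always closes at diagnosis.
#'
#' @param cohort a \code{gp_cohort} of eligible patients.
#' @return data frame with columns \code{patient_id} and \code{start_day}
#'   (integer days before diagnosis, in 1--730).
#' @export
observation_window <- function(cohort) {
  e <- cohort$encounters
  e <- e[e$days_before >= 1 & e$days_before <= 730, , drop = FALSE]
  ids <- cohort$patients$patient_id
  if (!all(ids %in% e$patient_id))
    stop("patient(s) without any encounter in the 730 days before diagnosis: ",
         paste(utils::head(setdiff(ids, e$patient_id), 5), collapse = ", "))
  by_id <- split(e$days_before, e$patient_id)[ids]
  start <- vapply(by_id, function(d) {
    if (any(d > 365) && any(d <= 365)) 730L else max(d)
  }, integer(1))
  data.frame(patient_id = ids, start_day = unname(start),
             stringsAsFactors = FALSE)
}

#' Active GP follow-up time
#'
#' Days from the first GP encounter in the two years before diagnosis until
#' the diagnosis date, counting a patient as actively followed only while
#' they have at least one encounter per year: whenever two consecutive
#' encounters (or the last encounter and diagnosis) are more than 365 days
#' apart, follow-up restarts at the first encounter after that gap.
#'
#' @param cohort a \code{gp_cohort} of eligible patients.
#' @return data frame with columns \code{patient_id} and \code{days}.
#' @export
active_followup_days <- function(cohort) {
  e <- cohort$encounters
  e <- e[e$days_before >= 1 & e$days_before <= 730, , drop = FALSE]
  ids <- cohort$patients$patient_id
  by_id <- split(e$days_before, e$patient_id)[ids]
  days <- vapply(by_id, function(d) {
    d <- sort(unique(d))           # ascending: nearest diagnosis first
    cur <- 0L                      # diagnosis day is the terminal endpoint
    for (di in d) {
      if (di - cur > 365L) break
      cur <- di
    }
    cur
  }, integer(1))
  data.frame(patient_id = ids, days = unname(days), stringsAsFactors = FALSE)
}

#' Pre-diagnosis month index
#'
#' Events are binned into 24 fixed 30-day months counted back from the day
#' before diagnosis: month -1 covers days 1--30 before diagnosis, month -2
#' days 31--60, ..., month -24 days 691--720. The diagnosis day itself
#' (day 0) and days beyond 720 fall outside the window.
#'
#' @param days_before integer vector of days strictly before diagnosis
#'   (non-negative).
#' @return integer vector of month indices in \code{-24...-1}, with \code{NA}
#'   for out-of-window days.
#' @export
month_index <- function(days_before) {
  if (any(days_before < 0, na.rm = TRUE))
    stop("days_before must be non-negative (events after diagnosis are invalid)")
  m <- -as.integer(ceiling(days_before / 30))
  m[days_before < 1 | days_before > 720] <- NA_integer_
  m
}

#' Drop screen-detected patients (sensitivity analysis)
#'
#' Patients whose cancer was recorded as detected through screening can be
#' excluded to check that pre-diagnostic testing signals are not driven by
#' screening pathways.
#'
#' @param cohort a \code{gp_cohort}.
#' @param exclude logical; if \code{FALSE} the cohort is returned unchanged.
#' @return the (possibly reduced) cohort; warns if it becomes empty.
#' @export
filter_screen_detected <- function(cohort, exclude = TRUE) {
  if (!exclude) return(cohort)
  keep <- cohort$patients$patient_id[!cohort$patients$screen_detected]
  if (!length(keep))
    warning("all patients are screen-detected; cohort is empty")
  subset_cohort(cohort, keep)
}
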