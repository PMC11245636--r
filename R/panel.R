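#' Qualifying events for monthly panels
#'
#' \code{request_events} extracts blood-test request events: one event per
#' distinct (patient, date) on which at least one assay of the requested
#' group was performed. \code{abnormal_events} extracts abnormal-result
#' events: one event per distinct (patient, date, logical analyte) whose
#' result is abnormal in the direction of clinical interest; for the
#' composites, events from all member analytes count (so a date with both
#' low albumin and raised platelets contributes two abnormal APR events).
#' CRP and ESR collapse to one inflammatory-marker event per date (raised
#' if either assay is raised).
#'
#' @param cohort a \code{\link{classify_cohort}} result.
#' @param group for requests: \code{"FBC"} (any full-blood-count component),
#'   \code{"APR"} (any acute phase reactant), or a standalone logical
#'   analyte (\code{"inflammatory_marker"}, \code{"ferritin"},
#'   \code{"albumin"}).
#' @param selector for abnormalities: a logical analyte name, or
#'   \code{"any_APR"} / \code{"any_RBCI"} for the composite signatures.
#' @return data frame of events with columns \code{patient_id},
#'   \code{days_before}, \code{month}, \code{in_window}.
#' @export
request_events <- function(cohort, group = "FBC") {
  stopifnot(inherits(cohort, "classified_cohort"))
  t <- cohort$tests
  an <- cohort$catalog$analytes
  sel <- switch(group,
    FBC = t$analyte %in% an$assay[an$panel == "FBC"],
    APR = t$group == "APR",
    t$analyte_logical == group)
  if (!any(sel) && !group %in% c("FBC", "APR") &&
      !group %in% an$analyte)
    stop("unknown request group: ", group)
  ev <- t[sel, c("patient_id", "days_before", "month", "in_window")]
  ev <- ev[!duplicated(paste(ev$patient_id, ev$days_before)), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @rdname request_events
#' @export
abnormal_events <- function(cohort, selector = "any_APR") {
  stopifnot(inherits(cohort, "classified_cohort"))
  t <- cohort$tests
  members <- composite_members(selector, cohort$catalog)
  sel <- t$of_interest & t$analyte_logical %in% members
  ev <- t[sel, c("patient_id", "days_before", "month", "in_window",
                 "analyte_logical")]
  ev <- ev[!duplicated(paste(ev$patient_id, ev$days_before, ev$analyte_logical)), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# logical analytes contributing to a selector
composite_members <- function(selector, catalog) {
  an <- catalog$analytes
  switch(selector,
    any_APR = unique(an$analyte[an$group == "APR"]),
    any_RBCI = unique(an$analyte[an$group == "RBCI"]),
    {
      if (!selector %in% an$analyte)
        stop("unknown analyte or composite: ", selector)
      selector
    })
}

#' Build a monthly event-rate panel
#'
#' Aggregates qualifying events into the 24 fixed 30-day months before
#' diagnosis. For each month the panel holds the at-risk count (patients
#' whose observation window covers any day of the month), the event count
#' (all qualifying in-window events; several events by one patient in a
#' month all count) and the rate per 1000 patients per month.
#'
#' @param cohort a \code{\link{classify_cohort}} result (supplies the
#'   observation windows).
#' @param events event data frame from \code{\link{request_events}} or
#'   \code{\link{abnormal_events}}.
#' @param label character tag stored on the panel.
#' @param denominator \code{"at_risk"} (default) uses the windowed at-risk
#'   count N_m; \code{"cohort"} uses the fixed full cohort size in every
#'   month.
#' @return data frame of class \code{monthly_panel} with columns
#'   \code{month}, \code{at_risk}, \code{events}, \code{rate_per_1000};
#'   months with no at-risk patients carry \code{NA} rate and are excluded
#'   from model fitting.
#' @export
build_panel <- function(cohort, events, label = "events",
                        denominator = c("at_risk", "cohort")) {
  stopifnot(inherits(cohort, "classified_cohort"))
  denominator <- match.arg(denominator)
  months <- -24:-1
  start <- cohort$windows$start_day
  at_risk <- if (denominator == "at_risk")
    vapply(months, function(m) sum(start > 30L * (-m - 1L)), integer(1))
  else rep(nrow(cohort$patients), 24L)
  ev <- events[events$in_window & !is.na(events$month), , drop = FALSE]
  e_m <- as.integer(table(factor(ev$month, levels = months)))
  rate <- ifelse(at_risk > 0, 1000 * e_m / at_risk, NA_real_)
  if (any(at_risk == 0))
    warning("month(s) with no at-risk patients: rate undefined there")
  structure(data.frame(month = months, at_risk = at_risk, events = e_m,
                       rate_per_1000 = rate),
            label = label, denominator = denominator,
            class = c("monthly_panel", "data.frame"))
}

#' Monthly incident and cumulative tested proportions
#'
#' The extent of testing over time: the incident series is the percentage
#' of at-risk patients with at least one qualifying request in each month
#' (a patient tested twice in a month counts once); the cumulative series
#' is the percentage of the whole cohort tested at least once between month
#' -24 and each month, and is nondecreasing.
#'
#' @param cohort a \code{\link{classify_cohort}} result.
#' @param group request group as in \code{\link{request_events}}.
#' @param denominator at-risk or fixed-cohort denominator for the incident
#'   series (the cumulative series always uses the full cohort size).
#' @return data frame with columns \code{month}, \code{at_risk},
#'   \code{patients_tested}, \code{incident_pct}, \code{cumulative_pct}.
#' @export
proportion_tested <- function(cohort, group = "FBC",
                              denominator = c("at_risk", "cohort")) {
  denominator <- match.arg(denominator)
  ev <- request_events(cohort, group)
  ev <- ev[ev$in_window & !is.na(ev$month), , drop = FALSE]
  months <- -24:-1
  start <- cohort$windows$start_day
  at_risk <- if (denominator == "at_risk")
    vapply(months, function(m) sum(start > 30L * (-m - 1L)), integer(1))
  else rep(nrow(cohort$patients), 24L)
  n_tested <- vapply(months, function(m)
    length(unique(ev$patient_id[ev$month == m])), integer(1))
  cum <- vapply(months, function(m)
    length(unique(ev$patient_id[ev$month <= m])), integer(1))
  data.frame(month = months, at_risk = at_risk, patients_tested = n_tested,
             incident_pct = ifelse(at_risk > 0, 100 * n_tested / at_risk, NA_real_),
             cumulative_pct = 100 * cum / nrow(cohort$patients))
}

#' Centred moving average with truncated edges
#'
#' Smooths a monthly series by the centred mean over a window of odd width;
#' at the edges the window is truncated to the available neighbours, so a
#' length-3 window averages two points at each end.
#'
#' @param x numeric series.
#' @param width odd window width; \code{width = 1} is the identity.
#' @return smoothed numeric series of the same length.
#' @export
moving_average <- function(x, width = 3) {
  if (!length(x)) stop("empty series")
  stopifnot(width >= 1, width %% 2 == 1)
  h <- (width - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)], na.rm = TRUE), numeric(1))
}
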