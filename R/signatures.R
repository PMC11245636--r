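#' Composite abnormality definitions
#'
#' The two composite signature variables: \code{any_APR} is abnormal when
#' any acute phase reactant is abnormal in its direction of interest
#' (raised platelets, low albumin, raised inflammatory marker, raised or
#' low ferritin, raised WBC); \code{any_RBCI} when any red-cell index is
#' (low haemoglobin, low haematocrit, low MCHC, low MCV, low RBC count,
#' raised RBCDW).
#'
#' @param catalog analyte catalogue.
#' @return data frame with columns \code{composite}, \code{analyte},
#'   \code{direction}.
#' @export
composite_definitions <- function(catalog = default_catalog()) {
  an <- catalog$analytes
  an <- an[!duplicated(an$analyte), , drop = FALSE]
  rows <- lapply(seq_len(nrow(an)), function(i) {
    dirs <- c(if (an$low_of_interest[i]) "low", if (an$high_of_interest[i]) "high")
    data.frame(composite = paste0("any_", an$group[i]), analyte = an$analyte[i],
               direction = dirs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-patient in-window of-interest abnormalities within the signature window
signature_tests <- function(cohort, window_days = 365) {
  stopifnot(inherits(cohort, "classified_cohort"))
  t <- cohort$tests
  t[t$in_window & t$days_before <= window_days, , drop = FALSE]
}

#' Tested and abnormal proportions in the year before diagnosis
#'
#' For each analyte and for the two composites, counts patients with at
#' least one result in the signature window (default the 12 months before
#' diagnosis) and, among those tested, patients with at least one
#' abnormality in the direction of interest — the denominator convention of
#' per-test abnormality tables (abnormal percentages are out of patients
#' tested, not the whole cohort). Ferritin appears once per direction.
#'
#' @param cohort a \code{\link{classify_cohort}} result.
#' @param window_days signature window in days before diagnosis.
#' @return data frame with columns \code{label}, \code{analyte},
#'   \code{direction}, \code{n_tested}, \code{pct_tested} (of the cohort),
#'   \code{n_abnormal}, \code{pct_abnormal} (of tested; \code{NA} and
#'   flagged when nobody was tested).
#' @export
tested_and_abnormal_table <- function(cohort, window_days = 365) {
  t <- signature_tests(cohort, window_days)
  n_cohort <- nrow(cohort$patients)
  defs <- composite_definitions(cohort$catalog)
  tested_ids <- function(analytes)
    unique(t$patient_id[t$analyte_logical %in% analytes])
  abnormal_ids <- function(analytes, direction = NULL) {
    sel <- t$of_interest & t$analyte_logical %in% analytes
    if (!is.null(direction)) sel <- sel & t$direction == direction
    unique(t$patient_id[sel])
  }
  one_row <- function(label, analytes, direction = NULL) {
    n_t <- length(tested_ids(analytes))
    n_a <- length(abnormal_ids(analytes, direction))
    data.frame(label = label,
               analyte = if (length(analytes) == 1) analytes else label,
               direction = if (is.null(direction)) "any" else direction,
               n_tested = n_t, pct_tested = 100 * n_t / n_cohort,
               n_abnormal = n_a,
               pct_abnormal = if (n_t > 0) 100 * n_a / n_t else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (comp in c("any_APR", "any_RBCI")) {
    d <- defs[defs$composite == comp, , drop = FALSE]
    rows[[comp]] <- one_row(comp, unique(d$analyte))
    for (i in seq_len(nrow(d)))
      rows[[paste(comp, i)]] <- one_row(
        paste(ifelse(d$direction[i] == "low", "low", "raised"), d$analyte[i]),
        d$analyte[i], d$direction[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$flagged <- out$n_tested == 0
  out
}

# per-patient day of first (earliest-in-time, i.e. largest days-before)
# of-interest abnormality among the given logical analytes
first_abnormal_days <- function(cohort, analytes, window_days = 365) {
  t <- signature_tests(cohort, window_days)
  t <- t[t$of_interest & t$analyte_logical %in% analytes, , drop = FALSE]
  if (!nrow(t)) return(integer(0))
  vapply(split(t$days_before, t$patient_id), max, integer(1))
}

#' Anaemia precedence of blood-test abnormalities
#'
#' Anaemia is the classical alarm blood-test finding; this analysis asks
#' how often other abnormalities of interest appear before it, or without
#' it ever appearing. Among patients with at least one abnormality of
#' interest in the signature window, each patient falls in exactly one
#' category: \emph{no anaemia} (haemoglobin never below the sex-specific
#' bound in the window), \emph{other abnormality first} (anaemia present
#' but another abnormality detected strictly earlier), or \emph{anaemia
#' first or tied}. By default a same-day tie counts as anaemia-first, the
#' conservative choice for the "before or in the absence of anaemia"
#' percentage; \code{tie = "other_first"} flips it.
#'
#' @param cohort a \code{\link{classify_cohort}} result.
#' @param window_days signature window in days before diagnosis.
#' @param tie how to classify a same-day first anaemia and first other
#'   abnormality.
#' @return An object of class \code{precedence_summary}: a list with
#'   \code{n_with_abnormality}, \code{n_no_anaemia}, \code{n_other_first},
#'   \code{n_anaemia_first_or_tied} (the three categories partition the
#'   total) and \code{percent_before_or_absent} = 100 (no-anaemia +
#'   other-first) / total.
#' @export
anaemia_precedence <- function(cohort, window_days = 365,
                               tie = c("anaemia_first", "other_first")) {
  tie <- match.arg(tie)
  an <- cohort$catalog$analytes
  all_analytes <- unique(an$analyte)
  other <- setdiff(all_analytes, "haemoglobin")
  d_any <- first_abnormal_days(cohort, all_analytes, window_days)
  d_hb <- first_abnormal_days(cohort, "haemoglobin", window_days)
  d_other <- first_abnormal_days(cohort, other, window_days)
  ids <- names(d_any)
  hb <- d_hb[ids]        # NA where anaemia absent
  ot <- d_other[ids]
  no_anaemia <- is.na(hb)
  # "first" = earlier in time = more days before diagnosis
  other_first <- !no_anaemia & !is.na(ot) &
    (ot > hb | (ot == hb & tie == "other_first"))
  n <- length(ids)
  out <- list(n_with_abnormality = n,
              n_no_anaemia = sum(no_anaemia),
              n_other_first = sum(other_first),
              n_anaemia_first_or_tied = sum(!no_anaemia & !other_first),
              tie = tie)
  out$percent_before_or_absent <-
    if (n > 0) 100 * (out$n_no_anaemia + out$n_other_first) / n else NA_real_
  class(out) <- "precedence_summary"
  out
}

#' @export
print.precedence_summary <- function(x, ...) {
  cat("Anaemia precedence (", x$n_with_abnormality,
      " patients with an abnormality of interest)\n", sep = "")
  cat("  no anaemia:           ", x$n_no_anaemia, "\n")
  cat("  other abnormality 1st:", x$n_other_first, "\n")
  cat("  anaemia first or tied:", x$n_anaemia_first_or_tied, "\n")
  cat(sprintf("  abnormality before or in the absence of anaemia: %.1f%% (prints as %d%%)\n",
              x$percent_before_or_absent, round(x$percent_before_or_absent)))
  invisible(x)
}

#' Timing of the first abnormal result before diagnosis
#'
#' For patients with at least one abnormality of interest for the given
#' analyte (or composite) in the signature window, summarises the number of
#' days before diagnosis at which the first such abnormality was detected:
#' median and interquartile range (linear-interpolation quantiles), mean and
#' sample standard deviation, and range.
#'
#' @param cohort a \code{\link{classify_cohort}} result.
#' @param selector a logical analyte name or \code{"any_APR"} /
#'   \code{"any_RBCI"}.
#' @param window_days signature window in days before diagnosis.
#' @return An object of class \code{timing_summary}: a list with \code{n},
#'   \code{days} (per-patient first-abnormality days), \code{median},
#'   \code{q1}, \code{q3}, \code{mean}, \code{sd} (0 with
#'   \code{sd_undefined = TRUE} when n < 2), \code{min}, \code{max}.
#' @export
first_abnormal_timing <- function(cohort, selector = "any_APR",
                                  window_days = 365) {
  members <- composite_members(selector, cohort$catalog)
  d <- first_abnormal_days(cohort, members, window_days)
  n <- length(d)
  if (n == 0)
    return(structure(list(selector = selector, n = 0L, days = integer(0)),
                     class = "timing_summary"))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(selector = selector, n = n, days = unname(d),
                 median = q[2], q1 = q[1], q3 = q[3],
                 mean = mean(d),
                 sd = if (n >= 2) stats::sd(d) else 0,
                 sd_undefined = n < 2,
                 min = min(d), max = max(d)),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  if (x$n == 0) {
    cat("First-abnormality timing (", x$selector, "): no qualifying patients\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("First-abnormality timing (%s): n = %d\n", x$selector, x$n))
  cat(sprintf("  median %.0f days before diagnosis (IQR %.0f-%.0f), mean %.1f (SD %.1f), range %d-%d\n",
              x$median, x$q1, x$q3, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Compare first-abnormality timing between two cohorts
#'
#' Welch two-sample t-test on the per-patient days-before-diagnosis of the
#' first abnormality of interest, comparing two cancer cohorts for one
#' analyte or composite.
#'
#' @param cohort_a,cohort_b \code{\link{classify_cohort}} results.
#' @param selector analyte or composite, as in
#'   \code{\link{first_abnormal_timing}}.
#' @param window_days signature window in days before diagnosis.
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{mean_a},
#'   \code{mean_b}, \code{n_a}, \code{n_b}; all statistics \code{NA} with a
#'   warning when either group has fewer than two patients.
#' @export
compare_timing <- function(cohort_a, cohort_b, selector = "any_APR",
                           window_days = 365) {
  a <- first_abnormal_timing(cohort_a, selector, window_days)
  b <- first_abnormal_timing(cohort_b, selector, window_days)
  if (a$n < 2 || b$n < 2) {
    warning("fewer than 2 qualifying patients in a group; t-test undefined")
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_a = if (a$n) a$mean else NA_real_,
                mean_b = if (b$n) b$mean else NA_real_,
                n_a = a$n, n_b = b$n))
  }
  tt <- stats::t.test(a$days, b$days, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = a$mean, mean_b = b$mean,
       n_a = a$n, n_b = b$n)
}
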