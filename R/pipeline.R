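#' Analysis run configuration
#'
#' Collects the tunable parameters of the end-to-end pipeline: the
#' catalogue, window lengths, the candidate inflexion grid, significance
#' level, denominator and tie conventions, and smoothing width.
#'
#' @param catalog analyte catalogue (or a YAML path for
#'   \code{\link{read_catalog}}).
#' @param panel_months rate-panel window in months before diagnosis
#'   (fixed at 24 in this release).
#' @param signature_window_days signature window for the abnormality
#'   analyses, in days (default 365, the year before diagnosis).
#' @param candidates candidate inflexion months.
#' @param alpha significance level for the inflexion null comparison.
#' @param denominator \code{"at_risk"} or \code{"cohort"} rate denominators.
#' @param tie same-day anaemia tie handling
#'   (\code{\link{anaemia_precedence}}).
#' @param ma_width moving-average width (odd).
#' @param exclude_screen_detected drop screen-detected patients before
#'   analysis (sensitivity analysis).
#' @return a \code{run_config} list.
#' @export
run_config <- function(catalog = default_catalog(),
                       panel_months = 24,
                       signature_window_days = 365,
                       candidates = -23:-2,
                       alpha = 0.05,
                       denominator = c("at_risk", "cohort"),
                       tie = c("anaemia_first", "other_first"),
                       ma_width = 3,
                       exclude_screen_detected = FALSE) {
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  validate_catalog(catalog)
  stopifnot(panel_months == 24, signature_window_days > 0,
            alpha > 0, alpha < 1, ma_width >= 1, ma_width %% 2 == 1)
  denominator <- match.arg(denominator)
  tie <- match.arg(tie)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pre-diagnostic activity pipeline
#'
#' Executes every analysis stage on one cohort: read (if a directory is
#' given), eligibility, screen-detected filtering, unit canonicalisation,
#' plausibility filtering, same-day deduplication, classification,
#' windowing, monthly request and abnormality panels with change-point fits
#' and rate ratios, tested proportions, the signature table, anaemia
#' precedence and first-abnormality timing. Deterministic: identical inputs
#' and configuration give identical outputs.
#'
#' @param cohort a \code{\link{gp_cohort}}, or a directory containing
#'   \code{patients.csv}, \code{encounters.csv}, \code{tests.csv}.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as CSV/JSON along with a manifest.
#' @return A list of class \code{pipeline_result}:
#'   \item{cohort}{the classified cohort used.}
#'   \item{request_panels, abnormal_panels}{named lists of
#'     \code{\link{build_panel}} results (requests: FBC, APR,
#'     inflammatory_marker, ferritin, albumin; abnormalities: the two
#'     composites and each logical analyte), each with \code{smoothed_rate}
#'     added.}
#'   \item{changepoints}{\code{\link{fit_changepoint}} per panel (where
#'     estimable).}
#'   \item{rate_ratio_tables}{\code{\link{rate_ratios}} per request panel.}
#'   \item{tested_proportions}{\code{\link{proportion_tested}} for FBC and
#'     APR.}
#'   \item{signature_table}{\code{\link{tested_and_abnormal_table}}.}
#'   \item{precedence}{\code{\link{anaemia_precedence}}.}
#'   \item{timing}{\code{\link{first_abnormal_timing}} per analyte and
#'     composite.}
#'   \item{exclusions}{row counts excluded at each stage with reasons.}
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  if (is.character(cohort))
    cohort <- read_cohort(file.path(cohort, "patients.csv"),
                          file.path(cohort, "encounters.csv"),
                          file.path(cohort, "tests.csv"))
  n_input <- nrow(cohort$patients)
  cohort <- eligible_cohort(cohort)
  n_inelig <- n_input - nrow(cohort$patients)
  n_screen <- 0L
  if (config$exclude_screen_detected) {
    n0 <- nrow(cohort$patients)
    cohort <- filter_screen_detected(cohort, TRUE)
    n_screen <- n0 - nrow(cohort$patients)
  }
  cc <- classify_cohort(cohort, config$catalog)

  req_groups <- c("FBC", "APR", "inflammatory_marker", "ferritin", "albumin")
  request_panels <- lapply(req_groups, function(g)
    add_smoothed(build_panel(cc, request_events(cc, g), paste0("requests_", g),
                             config$denominator), config$ma_width))
  names(request_panels) <- req_groups

  abn_sel <- c("any_APR", "any_RBCI", unique(cc$catalog$analytes$analyte))
  abnormal_panels <- lapply(abn_sel, function(s)
    add_smoothed(build_panel(cc, abnormal_events(cc, s), paste0("abnormal_", s),
                             config$denominator), config$ma_width))
  names(abnormal_panels) <- abn_sel

  all_panels <- c(request_panels, abnormal_panels)
  changepoints <- lapply(all_panels, function(p)
    tryCatch(fit_changepoint(p, config$candidates, config$alpha),
             error = function(e) NULL, warning = function(w)
               suppressWarnings(fit_changepoint(p, config$candidates,
                                                config$alpha))))
  rate_ratio_tables <- lapply(request_panels, function(p)
    tryCatch(rate_ratios(p), error = function(e) rate_ratios(p, pool_baseline = TRUE)))

  res <- list(
    cohort = cc,
    request_panels = request_panels,
    abnormal_panels = abnormal_panels,
    changepoints = changepoints,
    rate_ratio_tables = rate_ratio_tables,
    tested_proportions = list(
      FBC = proportion_tested(cc, "FBC", config$denominator),
      APR = proportion_tested(cc, "APR", config$denominator)),
    signature_table = tested_and_abnormal_table(cc, config$signature_window_days),
    precedence = anaemia_precedence(cc, config$signature_window_days, config$tie),
    timing = lapply(stats::setNames(abn_sel, abn_sel), function(s)
      first_abnormal_timing(cc, s, config$signature_window_days)),
    exclusions = data.frame(
      stage = c("ineligible", "screen_detected", "implausible_result"),
      n = c(n_inelig, n_screen, nrow(cc$rejected))),
    config = config)
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

add_smoothed <- function(panel, width) {
  panel$smoothed_rate <- moving_average(panel$rate_per_1000, width)
  panel
}

# serialise every result table; file set doubles as the pipeline manifest
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$request_panels))
    utils::write.csv(res$request_panels[[nm]],
                     file.path(out_dir, paste0("panel_requests_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(res$abnormal_panels))
    utils::write.csv(res$abnormal_panels[[nm]],
                     file.path(out_dir, paste0("panel_abnormal_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(res$rate_ratio_tables))
    utils::write.csv(res$rate_ratio_tables[[nm]],
                     file.path(out_dir, paste0("rate_ratios_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(res$signature_table, file.path(out_dir, "signature_table.csv"),
                   row.names = FALSE)
  cps <- lapply(res$changepoints, function(cp) if (is.null(cp)) NULL else
    cp[c("k_star", "beta0", "beta1", "log_likelihood", "AIC",
         "null_log_likelihood", "lrt_stat", "p_value", "no_inflexion")])
  jsonlite::write_json(cps, file.path(out_dir, "changepoints.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(res$precedence), file.path(out_dir, "precedence.json"),
                       auto_unbox = TRUE, digits = NA)
  timing <- do.call(rbind, lapply(res$timing, function(x)
    if (x$n == 0) NULL else
      data.frame(selector = x$selector, n = x$n, median = x$median,
                 q1 = x$q1, q3 = x$q3, mean = x$mean, sd = x$sd,
                 min = x$min, max = x$max)))
  utils::write.csv(timing, file.path(out_dir, "timing.csv"), row.names = FALSE)
  utils::write.csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
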