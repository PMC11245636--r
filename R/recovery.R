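#' Inflexion-point recovery study
#'
#' Simulates replicate cohorts with a known injected inflexion month and
#' re-estimates it from each, the standard calibration check that the
#' sequential hinge Poisson procedure recovers the diagnostic window under
#' the generator's own model family. Each replicate generates a cohort,
#' applies eligibility and classification, builds the full-blood-count
#' request panel and fits \code{\link{fit_changepoint}}.
#'
#' @param config a \code{\link{sim_config}}; its \code{seed} is replaced by
#'   each element of \code{seeds} in turn.
#' @param seeds integer vector, one replicate per seed.
#' @param candidates candidate inflexion months passed to
#'   \code{\link{fit_changepoint}}.
#' @return data frame with one row per replicate: \code{seed},
#'   \code{k_star}, \code{no_inflexion}.
#' @export
inflexion_recovery <- function(config, seeds, candidates = -23:-2) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    co <- simulate_cohort(cfg)
    cc <- suppressMessages(classify_cohort(eligible_cohort(co)))
    fit <- fit_changepoint(build_panel(cc, request_events(cc, "FBC"),
                                       "requests_FBC"),
                           candidates = candidates)
    data.frame(seed = s, k_star = fit$k_star, no_inflexion = fit$no_inflexion)
  })
  do.call(rbind, rows)
}
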