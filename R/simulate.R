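#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pre-diagnostic
#' analysis assumes: each patient has a stream of GP encounters over the 24
#' months before diagnosis (Poisson counts per 30-day month), and in each
#' month a full-blood-count panel is requested with a probability that is
#' constant at baseline and grows log-linearly after a known injected
#' inflexion month. A panel request emits same-day results for all FBC
#' components (haemoglobin, haematocrit, RBC count, RBCDW, MCV, MCHC,
#' platelets, WBC) plus, with their own probabilities, albumin, an
#' inflammatory marker (CRP or ESR) and ferritin. Result values are drawn
#' from a truncated normal centred inside the sex-specific reference range,
#' displaced beyond the abnormal-direction bound with a probability that
#' grows by the same hinge schedule.
#'
#' With inflexion month \eqn{k} and growth factor \eqn{g \ge 1}, the
#' request probability in month \eqn{m \in \{-24, ..., -1\}} is
#' \deqn{p_m = p_{base} \cdot g^{\max(0,\, m - k)},}
#' capped at 1 (with a warning), so month \eqn{k} itself is the last
#' baseline month — the same hinge the change-point estimator fits, which
#' makes parameter recovery well-posed. Defaults are the colorectal-cancer
#' study scale: 855 patients, baseline request probability 0.02, growth
#' 1.22/month after month -7; \code{lc_config()} gives the lung-cancer
#' scale (399 patients, 0.03, 1.20 after month -6).
#'
#' @param n_patients cohort size.
#' @param cancer_type \code{"CRC"} or \code{"LC"}.
#' @param encounter_rate_baseline expected GP encounters per patient-month
#'   (default 0.9, i.e. 10--11 visits/year).
#' @param test_request_prob_baseline baseline per-month probability of an
#'   FBC panel request.
#' @param inflexion_month integer in \code{-23...-2}, or \code{NA} for no
#'   inflexion (flat rates throughout).
#' @param monthly_growth multiplicative monthly growth in request
#'   probability after the inflexion month (>= 1).
#' @param abnormality_prob_baseline baseline probability that an emitted
#'   result is abnormal in its direction of interest; scalar or named
#'   vector by logical analyte.
#' @param abnormality_growth monthly multiplicative growth in that
#'   probability after the inflexion month; scalar or named vector.
#' @param albumin_prob,inflammatory_prob,ferritin_prob probability that a
#'   panel request also carries the standalone assay.
#' @param crp_share probability an inflammatory-marker request uses the CRP
#'   assay rather than ESR.
#' @param screen_detected_fraction fraction of patients flagged
#'   screen-detected (default 0.15, the CRC study figure; use 0 for LC).
#' @param seed integer seed; each patient draws from an independent stream
#'   derived from \code{(seed, patient index)}.
#' @return a \code{sim_config} list.
#' @seealso \code{\link{simulate_cohort}}
#' @export
sim_config <- function(n_patients = 855,
                       cancer_type = "CRC",
                       encounter_rate_baseline = 0.9,
                       test_request_prob_baseline = 0.02,
                       inflexion_month = -7,
                       monthly_growth = 1.22,
                       abnormality_prob_baseline = 0.1,
                       abnormality_growth = 1.15,
                       albumin_prob = 0.9,
                       inflammatory_prob = 0.4,
                       ferritin_prob = 0.5,
                       crp_share = 0.7,
                       screen_detected_fraction = 0.15,
                       seed = 1L) {
  stopifnot(n_patients >= 1, cancer_type %in% c("CRC", "LC"),
            monthly_growth >= 1, abnormality_growth >= 1,
            test_request_prob_baseline >= 0, test_request_prob_baseline <= 1,
            is.na(inflexion_month) ||
              (inflexion_month >= -23 && inflexion_month <= -2))
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to \code{sim_config}.
#' @export
lc_config <- function(...) {
  defaults <- list(n_patients = 399, cancer_type = "LC",
                   test_request_prob_baseline = 0.03,
                   inflexion_month = -6, monthly_growth = 1.20,
                   screen_detected_fraction = 0)
  args <- list(...)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hinge probability schedule over months -24..-1, capped at 1
hinge_prob <- function(base, growth, k, months = -24:-1) {
  expo <- if (is.na(k)) rep(0, length(months)) else pmax(0, months - k)
  p <- base * growth^expo
  if (any(p > 1)) {
    warning("growth schedule capped at probability 1")
    p <- pmin(p, 1)
  }
  p
}

# inverse-CDF truncated normal (vectorised, no rejection)
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a seeded synthetic cohort
#'
#' Draws the cohort described by a \code{\link{sim_config}}. Generation is
#' reproducible: patient \eqn{i} uses a pseudo-random stream seeded from
#' \code{(seed, i)}, so the same patient is identical across runs regardless
#' of generation order. Every simulated event date precedes diagnosis, and
#' every value lies within the catalogue's plausibility bounds.
#'
#' @param config a \code{\link{sim_config}}.
#' @param catalog analyte catalogue used for reference ranges when drawing
#'   values; defaults to \code{\link{default_catalog}()}.
#' @return a \code{\link{gp_cohort}} with attribute \code{"ledger"}: a data
#'   frame of the emitted FBC panel requests (\code{patient_id},
#'   \code{month}, \code{day_before}) for event-conservation checks, and
#'   attribute \code{"config"} recording the configuration.
#' @export
simulate_cohort <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  an <- catalog$analytes
  fbc <- an$assay[an$panel == "FBC"]
  months <- -24:-1
  p_req <- hinge_prob(config$test_request_prob_baseline,
                      config$monthly_growth, config$inflexion_month, months)
  q_base <- rep_len_named(config$abnormality_prob_baseline, an$analyte)
  q_growth <- rep_len_named(config$abnormality_growth, an$analyte)
  abn_expo <- if (is.na(config$inflexion_month)) rep(0, 24) else
    pmax(0, months - config$inflexion_month)

  # per-assay lookups by row of `an`
  w_m <- an$upper_ref_male - an$lower_ref_male
  w_f <- an$upper_ref_female - an$lower_ref_female

  n <- config$n_patients
  # accumulate plain vectors per patient; tables are assembled once at the
  # end (building data frames inside the loop dominates runtime otherwise)
  p_dx <- integer(n); p_sex <- character(n); p_age <- integer(n)
  p_scr <- logical(n)
  e_days <- vector("list", n)
  t_day <- vector("list", n); t_ai <- vector("list", n)
  t_val <- vector("list", n)
  l_mo <- vector("list", n); l_day <- vector("list", n)
  origin <- as.integer(as.Date("2016-01-01"))
  for (i in seq_len(n)) {
    set.seed(patient_stream_seed(config$seed, i))
    p_dx[i] <- origin + sample.int(1826L, 1L) - 1L
    sex <- if (stats::runif(1) < 0.57) "male" else "female"
    p_sex[i] <- sex
    p_age[i] <- min(95L, max(20L, as.integer(round(stats::rnorm(1, 65, 13)))))
    p_scr[i] <- stats::runif(1) < config$screen_detected_fraction

    # encounters: Poisson count per 30-day month, uniform day placement
    cnt <- stats::rpois(24L, config$encounter_rate_baseline)
    mo <- rep(months, cnt)
    enc_days <- 30L * (-mo - 1L) + sample.int(30L, sum(cnt), replace = TRUE)

    # panel requests per month; request day is a GP visit
    req <- stats::runif(24L) < p_req
    req_mo <- months[req]
    req_days <- 30L * (-req_mo - 1L) + sample.int(30L, sum(req), replace = TRUE)
    enc_days <- c(enc_days, req_days)
    if (!any(enc_days <= 365L))  # guarantee the qualifying pre-diagnosis visit
      enc_days <- c(enc_days, sample.int(30L, 1L))

    if (length(req_days)) {
      # assay set per request: all FBC components + standalones by coin flip
      per_req <- lapply(seq_along(req_days), function(j) {
        extra <- c(
          if (stats::runif(1) < config$albumin_prob) "albumin",
          if (stats::runif(1) < config$inflammatory_prob)
            (if (stats::runif(1) < config$crp_share) "crp" else "esr"),
          if (stats::runif(1) < config$ferritin_prob) "ferritin")
        cbind(j, match(c(fbc, extra), an$assay))
      })
      rows <- do.call(rbind, per_req)
      j <- rows[, 1]; ai <- rows[, 2]
      m_idx <- match(req_mo[j], months)
      q <- pmin(1, q_base[an$analyte[ai]] * q_growth[an$analyte[ai]]^abn_expo[m_idx])
      abn <- stats::runif(length(ai)) < q
      lo <- if (sex == "male") an$lower_ref_male[ai] else an$lower_ref_female[ai]
      hi <- if (sex == "male") an$upper_ref_male[ai] else an$upper_ref_female[ai]
      w <- if (sex == "male") w_m[ai] else w_f[ai]
      # abnormal direction: the analyte's direction of interest (ferritin
      # goes low or high with equal chance)
      go_low <- an$low_of_interest[ai] &
        (!an$high_of_interest[ai] | stats::runif(length(ai)) < 0.5)
      value <- numeric(length(ai))
      nrm <- !abn
      value[nrm] <- rtnorm(sum(nrm), (lo[nrm] + hi[nrm]) / 2, w[nrm] / 6,
                           lo[nrm], hi[nrm])
      al <- abn & go_low
      value[al] <- rtnorm(sum(al), lo[al] - w[al] / 3, w[al] / 4,
                          pmax(an$plausible_min[ai][al], 0.005 * w[al]), lo[al])
      ah <- abn & !go_low
      value[ah] <- rtnorm(sum(ah), hi[ah] + w[ah] / 3, w[ah] / 4,
                          hi[ah], an$plausible_max[ai][ah])
      t_day[[i]] <- req_days[j]; t_ai[[i]] <- ai; t_val[[i]] <- value
      l_mo[[i]] <- req_mo; l_day[[i]] <- req_days
    }
    e_days[[i]] <- sort(enc_days)
  }
  pid <- sprintf("P%05d", seq_len(n))
  dx <- as.Date(p_dx, origin = "1970-01-01")
  patients <- data.frame(
    patient_id = pid, cancer_type = config$cancer_type, diagnosis_date = dx,
    sex = p_sex, birth_year = as.integer(format(dx, "%Y")) - p_age,
    screen_detected = p_scr, stringsAsFactors = FALSE)
  n_enc <- lengths(e_days)
  encounters <- data.frame(
    patient_id = rep(pid, n_enc),
    date = as.Date(rep(p_dx, n_enc) - unlist(e_days), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  n_t <- lengths(t_day)
  ai <- unlist(t_ai)
  tests <- data.frame(
    patient_id = rep(pid, n_t),
    date = as.Date(rep(p_dx, n_t) - unlist(t_day), origin = "1970-01-01"),
    analyte = an$assay[ai], value = as.numeric(unlist(t_val)),
    unit = an$canonical_unit[ai], stringsAsFactors = FALSE)
  cohort <- gp_cohort(patients, encounters, tests)
  attr(cohort, "ledger") <- data.frame(
    patient_id = rep(pid, lengths(l_mo)), month = as.integer(unlist(l_mo)),
    day_before = as.integer(unlist(l_day)), stringsAsFactors = FALSE)
  attr(cohort, "config") <- config
  cohort
}

rep_len_named <- function(x, analytes) {
  u <- unique(analytes)
  if (is.null(names(x))) {
    out <- rep_len(x, length(u))
    names(out) <- u
  } else {
    if (!all(u %in% names(x)))
      stop("per-analyte vector missing: ",
           paste(setdiff(u, names(x)), collapse = ", "))
    out <- x[u]
  }
  out
}

# independent per-patient substream so cohorts are reproducible under
# reordering; stays within 32-bit integer range
patient_stream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483629)
}

#' Write a cohort to the three-CSV interchange format
#'
#' Emits \code{patients.csv}, \code{encounters.csv} and \code{tests.csv}
#' (UTF-8, ISO-8601 dates) plus, for simulated cohorts, \code{manifest.json}
#' recording the generator configuration. \code{\link{read_cohort}} on the
#' output reconstructs the cohort value-identically.
#'
#' @param cohort a \code{\link{gp_cohort}}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name, drop = "days_before") {
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  p <- cohort$patients
  p$screen_detected <- as.integer(p$screen_detected)
  wr(p, "patients.csv")
  wr(cohort$encounters, "encounters.csv")
  wr(cohort$tests, "tests.csv")
  cfg <- attr(cohort, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
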