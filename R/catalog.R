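#' Analyte catalogue for GP blood tests
#'
#' The analysis covers twelve blood tests: six acute phase reactants (APR) --
#' platelet count, inflammatory markers (CRP and ESR, considered together as
#' one logical analyte), white blood cell count, albumin and ferritin -- and
#' six red blood cell indices (RBCI) -- haemoglobin, haematocrit, RBC count,
#' red cell distribution width, mean cell volume and mean cell haemoglobin
#' concentration. The catalogue maps each laboratory assay code to its
#' logical analyte, analyte group, panel membership, canonical unit,
#' sex-specific reference range, plausibility bounds and the abnormal
#' direction(s) of clinical interest.
#'
#' Raised ferritin marks an acute phase response while low ferritin marks
#' iron deficiency, so ferritin is the only analyte with both directions of
#' interest. CRP and ESR are distinct assay rows (different units, never
#' averaged together) that map to the single logical analyte
#' \code{inflammatory_marker}; the marker is raised on a date if either assay
#' is above its upper bound.
#'
#' @return An object of class \code{analyte_catalog}: a list with components
#'   \item{analytes}{data frame, one row per assay code, with columns
#'     \code{assay}, \code{analyte} (logical analyte), \code{group}
#'     (\code{"APR"} or \code{"RBCI"}), \code{panel} (\code{"FBC"} or
#'     \code{"standalone"}), \code{canonical_unit},
#'     \code{lower_ref_male}, \code{upper_ref_male}, \code{lower_ref_female},
#'     \code{upper_ref_female}, \code{plausible_min}, \code{plausible_max},
#'     \code{low_of_interest}, \code{high_of_interest}.}
#'   \item{units}{data frame of accepted unit conversions with columns
#'     \code{assay}, \code{unit}, \code{factor}; multiplying a value by
#'     \code{factor} expresses it in the canonical unit.}
#'
#' @details Default reference ranges follow common adult laboratory
#' conventions (haemoglobin in g/dL, haematocrit as a fraction, MCHC in g/L
#' and so on); real laboratories vary, so every bound is configurable via
#' \code{\link{read_catalog}}. Plausibility bounds default to ten reference
#' widths beyond each reference bound (floored at zero), with wider upper
#' bounds for CRP, ESR and ferritin, whose pathological values routinely
#' exceed that rule.
#'
#' @seealso \code{\link{classify_results}}, \code{\link{canonicalise_units}},
#'   \code{\link{read_catalog}}
#' @export
default_catalog <- function() {
  an <- read.csv(text = "
assay,analyte,group,panel,canonical_unit,lower_ref_male,upper_ref_male,lower_ref_female,upper_ref_female,low_of_interest,high_of_interest
platelets,platelets,APR,FBC,10^9/L,150,400,150,400,FALSE,TRUE
crp,inflammatory_marker,APR,standalone,mg/L,0,5,0,5,FALSE,TRUE
esr,inflammatory_marker,APR,standalone,mm/h,0,15,0,20,FALSE,TRUE
wbc,wbc,APR,FBC,10^9/L,4,11,4,11,FALSE,TRUE
albumin,albumin,APR,standalone,g/L,35,50,35,50,TRUE,FALSE
ferritin,ferritin,APR,standalone,ug/L,30,300,15,200,TRUE,TRUE
haemoglobin,haemoglobin,RBCI,FBC,g/dL,13,17,12,16,TRUE,FALSE
hct,hct,RBCI,FBC,fraction,0.40,0.54,0.37,0.47,TRUE,FALSE
rbc_count,rbc_count,RBCI,FBC,10^12/L,4.5,6.5,3.8,5.8,TRUE,FALSE
rbcdw,rbcdw,RBCI,FBC,%,11.5,14.5,11.5,14.5,FALSE,TRUE
mcv,mcv,RBCI,FBC,fL,80,100,80,100,TRUE,FALSE
mchc,mchc,RBCI,FBC,g/L,320,360,320,360,TRUE,FALSE
", strip.white = TRUE, stringsAsFactors = FALSE)
  # plausibility: 10 reference widths beyond each bound, floored at 0
  width <- pmax(an$upper_ref_male - an$lower_ref_male,
                an$upper_ref_female - an$lower_ref_female)
  an$plausible_min <- pmax(0, pmin(an$lower_ref_male, an$lower_ref_female) - 10 * width)
  an$plausible_max <- pmax(an$upper_ref_male, an$upper_ref_female) + 10 * width
  # acute-phase analytes exceed the 10-width rule in real disease
  an$plausible_max[an$assay == "crp"] <- 500
  an$plausible_max[an$assay == "esr"] <- 180
  an$plausible_max[an$assay == "ferritin"] <- 10000
  units <- read.csv(text = "
assay,unit,factor
platelets,10^9/L,1
crp,mg/L,1
esr,mm/h,1
wbc,10^9/L,1
albumin,g/L,1
albumin,g/dL,10
ferritin,ug/L,1
ferritin,ng/mL,1
haemoglobin,g/dL,1
haemoglobin,g/L,0.1
hct,fraction,1
hct,%,0.01
rbc_count,10^12/L,1
rbcdw,%,1
mcv,fL,1
mchc,g/L,1
mchc,g/dL,10
", strip.white = TRUE, stringsAsFactors = FALSE)
  cat <- structure(list(analytes = an, units = units), class = "analyte_catalog")
  validate_catalog(cat)
  cat
}

#' Validate an analyte catalogue
#'
#' Checks the structural invariants of an \code{analyte_catalog}: twelve
#' assay rows mapping to eleven logical analytes (CRP and ESR share
#' \code{inflammatory_marker}), reference ranges ordered within plausibility
#' bounds for both sexes, ferritin (and only ferritin) carrying both abnormal
#' directions of interest, and every assay having a canonical unit with
#' conversion factor 1.
#'
#' @param catalog an \code{analyte_catalog}.
#' @return the catalogue, invisibly; errors if any invariant fails.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "analyte_catalog"))
  an <- catalog$analytes
  if (nrow(an) != 12L)
    stop("catalog must contain exactly 12 assay rows, got ", nrow(an))
  if (length(unique(an$analyte)) != 11L)
    stop("catalog must map to exactly 11 logical analytes")
  if (!identical(sort(an$assay[an$analyte == "inflammatory_marker"]), c("crp", "esr")))
    stop("inflammatory_marker must cover exactly the crp and esr assays")
  for (sex in c("male", "female")) {
    lo <- an[[paste0("lower_ref_", sex)]]
    hi <- an[[paste0("upper_ref_", sex)]]
    if (any(lo >= hi))
      stop("lower_ref must be < upper_ref for every assay and sex")
    if (any(an$plausible_min > lo) || any(an$plausible_max <= hi))
      stop("plausibility bounds must enclose the reference range")
  }
  both <- an$assay[an$low_of_interest & an$high_of_interest]
  if (!identical(both, "ferritin"))
    stop("ferritin, and only ferritin, has both abnormal directions of interest")
  if (any(!an$low_of_interest & !an$high_of_interest))
    stop("every assay needs at least one abnormal direction of interest")
  canon <- merge(an[, c("assay", "canonical_unit")], catalog$units,
                 by.x = c("assay", "canonical_unit"), by.y = c("assay", "unit"))
  if (nrow(canon) != nrow(an) || any(canon$factor != 1))
    stop("every assay needs its canonical unit listed with factor 1")
  invisible(catalog)
}

#' Read or write an analyte catalogue as YAML
#'
#' The catalogue serialises to a YAML document with one entry per assay plus
#' an accepted-units list, and round-trips value-identically.
#'
#' @param path file path.
#' @return \code{read_catalog}: an \code{analyte_catalog};
#'   \code{write_catalog}: \code{path}, invisibly.
#' @export
read_catalog <- function(path) {
  doc <- yaml::read_yaml(path)
  an <- do.call(rbind, lapply(doc$analytes, function(e)
    data.frame(e[setdiff(names(e), "accepted_units")], stringsAsFactors = FALSE)))
  units <- do.call(rbind, lapply(doc$analytes, function(e) {
    u <- e$accepted_units
    data.frame(assay = e$assay, unit = vapply(u, `[[`, "", "unit"),
               factor = vapply(u, function(x) as.numeric(x$factor), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(an) <- rownames(units) <- NULL
  cat <- structure(list(analytes = an, units = units), class = "analyte_catalog")
  validate_catalog(cat)
  cat
}

#' @rdname read_catalog
#' @param catalog an \code{analyte_catalog}.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  an <- catalog$analytes
  entries <- lapply(seq_len(nrow(an)), function(i) {
    e <- as.list(an[i, , drop = FALSE])
    e <- lapply(e, unname)
    u <- catalog$units[catalog$units$assay == an$assay[i], , drop = FALSE]
    e$accepted_units <- lapply(seq_len(nrow(u)), function(j)
      list(unit = u$unit[j], factor = u$factor[j]))
    e
  })
  # precision 17 keeps doubles bit-exact through the round-trip
  yaml::write_yaml(list(analytes = entries), path,
                   precision = 17, handlers = list(logical = yaml::verbatim_logical))
  invisible(path)
}

# internal: per-(assay, sex) reference bounds as a lookup data frame
ref_bounds <- function(catalog, sex) {
  an <- catalog$analytes
  data.frame(assay = an$assay,
             lower = an[[paste0("lower_ref_", sex)]],
             upper = an[[paste0("upper_ref_", sex)]],
             stringsAsFactors = FALSE)
}
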