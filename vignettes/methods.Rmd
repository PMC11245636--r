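---
title: "Methods: pre-diagnostic blood-test activity and the diagnostic window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-diagnostic blood-test activity and the diagnostic window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the months before a colorectal (CRC) or lung (LC) cancer diagnosis,
patients consult their GP more often and are sent for more blood tests,
and those tests are more often abnormal. Quantifying *when* that activity
first departs from its background level — the opening of the diagnostic
window — and *which* abnormalities appear first tells us how much earlier
a diagnosis might plausibly be reached from signals already present in
routine primary-care records. `prediagblood` implements that analysis as a
reusable pipeline over three flat tables (patients, GP encounters,
blood-test results), together with a synthetic-cohort generator that
stands in for linked registry/EHR data, which are not publicly available.

## Cohort rules

- **Eligibility**: age ≥ 18 at diagnosis and at least one GP encounter in
  the 365 days before diagnosis (day 365 inclusive; the diagnosis day
  itself, day 0, never counts as pre-diagnostic).
- **Observation window**: patients seen at least once in each of the two
  pre-diagnosis years are observable for the full 730 days; otherwise the
  window opens at the first encounter within 730 days. Events outside a
  patient's window are excluded, and the window drives the at-risk
  denominators below.
- **Active follow-up**: days from the first encounter within 730 days to
  diagnosis, restarting after any gap of more than 365 days between
  consecutive encounters (with diagnosis as the terminal endpoint). This
  is a descriptive statistic, not an analysis input.
- **Month bins**: events are assigned to 24 fixed 30-day bins counted back
  from the day before diagnosis (month −1 = days 1–30, ..., month −24 =
  days 691–720). Fixed-width bins make the panel exact and
  calendar-arithmetic-free; the cost is that "month" means 30 days, not a
  calendar month, a difference that cannot move an event by more than one
  bin.

## Result preparation

Twelve blood tests are analysed: six acute phase reactants (APR:
platelets, inflammatory markers, WBC, albumin, ferritin — with CRP and ESR
as two assays of the one logical inflammatory-marker analyte) and six red
blood cell indices (RBCI: haemoglobin, haematocrit, RBC count, RBCDW, MCV,
MCHC). Preparation runs in a fixed order: unit canonicalisation (e.g.
haemoglobin g/L ÷ 10 → g/dL), plausibility filtering (defaults: ten
reference widths beyond each bound, floored at zero, with wider upper
bounds for CRP, ESR and ferritin whose pathological values routinely
exceed that rule; rejected rows are logged, never silently dropped),
same-day deduplication to the arithmetic mean per (patient, day, assay),
and classification against sex-specific reference ranges.

Classification conventions worth stating explicitly:

- A value exactly on a reference bound is **normal**. Published analyses
  rarely state their boundary convention; ours is deterministic and
  documented, and since results are continuous measurements, boundary ties
  are rare enough not to matter in practice.
- Each analyte has a direction of clinical interest (low haemoglobin =
  anaemia, raised platelets, raised RBCDW, ...); ferritin alone is of
  interest in both directions (raised = acute-phase response, low = iron
  deficiency). Only abnormalities of interest feed the signature analyses.
- CRP and ESR are never averaged together (different units); deduplication
  is per assay, and the inflammatory marker counts as raised on a date if
  either assay is raised — one event per date, not two.
- Reference ranges default to common adult laboratory conventions
  (haemoglobin M 13–17 / F 12–16 g/dL, platelets 150–400 ×10⁹/L, and so
  on) and are fully configurable through the YAML catalogue
  (`read_catalog()`/`write_catalog()`), because the source laboratories'
  exact ranges are unknowable from outside.

## Monthly panels and the change-point model

For an event stream (test requests of some group, or abnormal results of
some analyte or composite) the panel holds, per month *m* ∈ {−24, ..., −1},
the at-risk count `N_m` (patients whose window covers any day of the
month), the event count `e_m`, and the rate per 1000 patients/month. The
at-risk denominator is the default because a fixed whole-cohort
denominator lets late window entries masquerade as rate rises; the
fixed-denominator variant is available as a switch for comparison.
Abnormal-event panels count abnormal *results*, not patients, so a patient
with abnormalities in three months contributes three events.

The inflexion point is estimated by sequential hinge Poisson regression.
For each candidate month *k* in −23...−2 (every candidate keeps at least
one baseline and one post-inflexion month):

$$e_m \sim \mathrm{Poisson}\!\left(N_m\, e^{\beta_0 + \beta_1 \max(0,\, m-k)}\right)$$

fitted by IRLS (`glm` with a log at-risk offset). The rate is constant at
`exp(β₀)` per patient-month up to and including month *k* and grows by a
factor `exp(β₁)` per month thereafter — the minimal model family matching
"the month when rates first start to increase from the background rate".
The candidate with maximum log-likelihood is selected; with equal
parameter counts this is also the minimum-AIC model, and ties within 1e−9
break toward the earlier month (the longer, more conservative-to-claim
diagnostic window). The selected model is compared with the constant-rate
null by a likelihood-ratio test on **2 degrees of freedom** — β₁ plus one
df as a conservative allowance for the searched *k*. The proper reference
distribution for a maximum over candidates is not chi-square; the 2-df
convention is a pragmatic, conservative choice, and our null simulations
(flat panels at study scale) flag an inflexion in well under 5% of
replicates. Panels whose test is non-significant at α = 0.05 are flagged
`no_inflexion`.

Rate ratios compare each month with the month −24 baseline,
`RR_m = (e_m/N_m)/(e_{−24}/N_{−24})`, with log-scale 95% intervals
`exp(log RR ± 1.96√(1/e_m + 1/e_{−24}))`; the series is invariant to
uniform denominator rescaling, zero-event months are flagged with RR 0,
and a zero baseline suggests the pooled −24...−22 baseline switch. Rate
ratios are empirical, not model-smoothed; modelled rates are recoverable
from the fitted hinge if wanted. Fold increases (month −1 over month −24)
are reported on the 3-month centred moving average by default — matching
how smoothed monthly-rate figures are read — with truncated windows at the
series edges, and on the raw series on request.

## Signature analyses

All signature analyses use the 12-month window (days 1–365, intersected
with the patient's observation window).

- **Tested/abnormal table**: per analyte and for the composites (any APR
  abnormality; any RBCI abnormality), the number tested (% of the cohort)
  and the number with an abnormality of interest (% *of those tested* —
  the published denominator convention).
- **Anaemia precedence**: among patients with any abnormality of interest,
  three mutually exclusive categories — never anaemic in the window;
  anaemia present but another abnormality strictly earlier; anaemia first
  or tied. "First" compares days before diagnosis (larger = earlier).
  Same-day ties count as anaemia-first by default: this is conservative
  for the headline percentage of patients whose abnormality came *before
  or in the absence of* anaemia; a switch flips the convention to check
  sensitivity.
- **Timing**: each patient's first (earliest-in-time) abnormality of
  interest, summarised by median and IQR (type-7 linear-interpolation
  quantiles — the published software convention is unknown, so we use R's
  default), mean, sample SD (n − 1; reported as 0 with a flag when n = 1),
  and range. Between-cancer comparisons use the Welch two-sample t-test
  rather than pooled-variance Student — the published analysis says only
  "t-test", and Welch is the safer default under unequal variances.

## The synthetic generator

`simulate_cohort()` draws, per patient: a diagnosis date (2016–2020), sex
(57% male), age (normal, mean 65, SD 13, truncated to 20–95), a
screen-detected flag, Poisson(0.9) GP encounters per 30-day month (≈ 10–11
visits/year, as seen in such cohorts) placed uniformly within the month,
and a full-blood-count request per month with probability

$$p_m = p_{\mathrm{base}} \cdot g^{\max(0,\, m - k_{\mathrm{true}})},$$

capped at 1 with a warning — the same hinge the estimator fits, so month
`k_true` is the last baseline month. Requests land on a GP-visit day and
emit same-day results for all eight FBC components plus albumin (p = 0.9),
an inflammatory marker (p = 0.4; CRP 70% / ESR 30%) and ferritin (p = 0.5),
roughly matching the relative request frequencies of standalone tests in
such cohorts. Values are truncated-normal inside the sex-specific
reference range (mean at the midpoint, SD = width/6, inverse-CDF
truncation, no rejection sampling); with probability
`q_m = q_base · a^{max(0, m − k_true)}` (defaults 0.1 and 1.15/month) the
value is instead displaced beyond the abnormal-direction bound (truncated
normal centred a third of a reference width beyond the bound, ferritin
choosing low/high with equal probability). Analytes are drawn
independently; a correlated anaemia/ferritin structure is deliberately not
simulated, since no joint distribution is available to calibrate against.

Default scales are the study conditions: CRC — 855 patients, `p_base` =
0.02, `g` = 1.22, `k_true` = −7, 15% screen-detected; LC (`lc_config()`) —
399 patients, 0.03, 1.20, `k_true` = −6. Reproducibility is per patient:
patient *i* draws from a stream seeded by (seed, *i*), so cohorts are
identical across runs and a cohort prefix is unchanged when the cohort
grows.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: overdispersion and within-patient clustering of
requests, seasonality and secular trends in testing, correlated analyte
panels, laboratory-to-laboratory reference-range variation, missingness
informative of severity, and any link between abnormality magnitude and
proximity to diagnosis beyond the hinge schedule. Recovery results
(median recovered inflexion month equal to the injected month over 200
replicates at each study scale, computed by `scripts/acceptance.R` and the
test suite) therefore validate the estimator under its own model family,
not the epidemiology.

## Numerical and degenerate-input choices

- Likelihood evaluation uses `lgamma(e + 1)` for log-factorials; the
  hand-written `poisson_loglik()` is the oracle surface for testing the
  `glm`-based fits (agreement within 1e−6 at the fitted optimum).
- Candidates that fail to converge are dropped with a warning; an
  all-dropped grid is an error. Fewer than six non-empty months is an
  error (the hinge has three effective parameters).
- Empty cohorts, months with zero at-risk patients, zero-event months,
  single-patient timing summaries and all-screen-detected cohorts are all
  defined, flagged outcomes rather than errors, as tested.
- Problem sizes: the test suite and acceptance script run 200 replicates
  per study scale (855 and 399 patients), chosen to bound the Monte-Carlo
  error of a median on an integer grid while keeping a full run within a
  few minutes on one CPU.

## Scope and limitations

The package estimates a single inflexion point per series; joinpoint-style
multiple change points, negative-binomial overdispersion, calendar-time
adjustment and age/sex standardisation are out of scope in this release,
as are record linkage itself and any clinical risk-prediction modelling.
No multiplicity correction is applied across the twelve analytes,
matching the descriptive intent of the signature tables. The workflow in
`analysis/` runs entirely on synthetic cohorts; applying it to real linked
data requires only the three-CSV interchange format and a
laboratory-specific catalogue.
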