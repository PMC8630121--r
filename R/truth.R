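# Published model estimates and descriptive ranges used as generator
# defaults and as ground truth for parameter-recovery experiments.

#' Default ground-truth coefficients for the generator
#'
#' Named coefficient vectors for the four outcomes, matching the term
#' layout of the preset specs ([spec_covid_hosp()] and friends). The
#' hospitalization vectors are the published estimates; the ICU
#' vectors reuse the hospitalization slopes with intercepts shifted to
#' the published ICU outcome means (ICU-specific estimates were not
#' published).
#'
#' @return Named list with one named numeric vector per outcome.
#' @export
truth_beta_defaults <- function() {
  covid_hosp <- c(
    "(Intercept)" = -20.151,
    case_lag2 = 1.266,
    "case_lag2:region_west" = -0.145,
    "case_lag2:region_south" = -0.694,
    wma_pct_diff = 0.089,
    "wma_pct_diff:region_midwest" = 0.177,
    "wma_pct_diff:region_south" = -0.038,
    wma_above = 0.058,
    ln_mob_lag2 = 0.157,
    ln_mob_lag3 = 0.295,
    young_pct = -0.051,
    hispanic_pct = 0.025,
    african_american_pct = 0.020,
    female_pct = 0.173,
    ln_median_income = 0.619,
    ln_cardio = 1.133,
    hepc_per_100k = 0.070,
    region_midwest = 0.111,
    region_northeast = -0.109,
    "region_northeast:since_wave2" = 0.204,
    top10_tourist = 0.243,
    "top10_tourist:since_wave2" = -0.114,
    airports_per_100k = 0.017,
    since_wave2 = 0.360,
    since_dec25 = 0.106
  )
  noncovid_hosp <- c(
    "(Intercept)" = -9.858,
    case_lag1 = -0.076,
    case_lag2 = -0.107,
    young_pct = -0.043,
    hispanic_pct = 0.008,
    african_american_pct = 0.002,
    female_pct = 0.153,
    ln_hiv = 0.236,
    ln_cancer = 0.973,
    since_dec25 = -0.041
  )
  covid_icu <- covid_hosp
  # shift to the published ICU outcome means (0.752 vs 1.935)
  covid_icu[["(Intercept)"]] <- covid_icu[["(Intercept)"]] - 1.183
  noncovid_icu <- noncovid_hosp
  # shift to the published ICU outcome means (1.536 vs 4.069)
  noncovid_icu[["(Intercept)"]] <- noncovid_icu[["(Intercept)"]] - 2.533
  list(
    ln_covid_hosp = covid_hosp,
    ln_noncovid_hosp = noncovid_hosp,
    ln_covid_icu = covid_icu,
    ln_noncovid_icu = noncovid_icu
  )
}

#' Default ground-truth covariance parameters
#'
#' The published (sigma2, phi, rho) triplets for the hospitalization
#' outcomes; ICU outcomes default to the matching hospitalization
#' triplet.
#'
#' @return Named list of [cov_params()] per outcome.
#' @export
truth_cov_defaults <- function() {
  list(
    ln_covid_hosp = cov_params(1.912, 0.835, 0.930),
    ln_noncovid_hosp = cov_params(1.370, 0.888, 0.965),
    ln_covid_icu = cov_params(1.912, 0.835, 0.930),
    ln_noncovid_icu = cov_params(1.370, 0.888, 0.965)
  )
}

#' Preset spec per outcome
#'
#' @param outcome One of [outcome_names()].
#' @return The matching preset [model_spec()].
#' @export
spec_for_outcome <- function(outcome) {
  outcome <- match.arg(outcome, outcome_names())
  switch(outcome,
    ln_covid_hosp = spec_covid_hosp(),
    ln_noncovid_hosp = spec_noncovid_hosp(),
    ln_covid_icu = spec_covid_icu(),
    ln_noncovid_icu = spec_noncovid_icu()
  )
}

#' Default static covariate ranges
#'
#' Min / mean / max per county-level covariate (log scale where the
#' model uses the log), used by the scaled-beta covariate draws of the
#' generator.
#'
#' @return Tibble with columns `variable`, `min`, `mean`, `max`, `log`.
#' @export
covariate_range_defaults <- function() {
  tribble(
    ~variable,              ~min,   ~mean,  ~max,    ~log,
    "young_pct",            7.155,  22.403, 35.987,  FALSE,
    "hispanic_pct",         0.653,  10.015, 96.322,  FALSE,
    "african_american_pct", 0.113,  9.720,  76.331,  FALSE,
    "female_pct",           37.041, 50.348, 56.145,  FALSE,
    "median_income",        10.149, 10.866, 11.821,  TRUE,
    "cardio_per_1000",      3.157,  4.119,  4.891,   TRUE,
    "hepc_per_100k",        0.000,  1.064,  5.600,   FALSE,
    "hiv_rate_per_100k",    0.723,  4.780,  7.859,   TRUE,
    "cancer_rate_per_100k", 5.489,  6.119,  6.436,   TRUE,
    "airports_per_100k",    0.000,  1.269,  24.927,  FALSE
  )
}
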