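#' Log per-100k rate transform
#'
#' The outcome transform for all four dependent variables: a weekly
#' count is converted to a rate per 100,000 residents and mapped through
#' `ln(1 + rate)`. The `1 +` offset reproduces the observed 0.000 floor
#' for zero-count county-weeks and makes the transform invertible with
#' [inv_log_rate()].
#'
#' @param count Nonnegative count (vectorised).
#' @param population County population, must be positive.
#' @return `ln(1 + 100000 * count / population)`, always `>= 0`.
#' @export
log_rate <- function(count, population) {
  if (any(population <= 0)) {
    stop_hospanel("population must be positive", class = "hospanel_domain_error")
  }
  if (any(count < 0)) {
    stop_hospanel("count must be nonnegative", class = "hospanel_domain_error")
  }
  log1p(1e5 * count / population)
}

#' Inverse of the log per-100k rate transform
#'
#' @param x Log-rate value(s).
#' @return Rate per 100,000: `exp(x) - 1`.
#' @export
inv_log_rate <- function(x) expm1(x)

#' Lag a weekly series
#'
#' Shifts a per-week series by `lag` weeks; the first `lag` positions
#' are `NA` (unavailable) and the corresponding panel rows are excluded
#' from model fitting.
#'
#' @param values Numeric per-week series.
#' @param lag Lag in weeks, one of 1, 2, 3.
#' @return Series of the same length with `values[t - lag]` at position
#'   `t`.
#' @export
lagged_series <- function(values, lag) {
  if (!is.numeric(lag) || length(lag) != 1 || !lag %in% c(1, 2, 3)) {
    stop_hospanel("lag must be 1, 2 or 3", class = "hospanel_parameter_error")
  }
  n <- length(values)
  if (n < lag + 1) {
    stop_hospanel("series shorter than lag + 1",
                  class = "hospanel_parameter_error")
  }
  c(rep(NA_real_, lag), values[seq_len(n - lag)])
}

#' Three-week moving-average features
#'
#' For each week `t`, computes the mean of the three *preceding* weeks
#' (`t-3 .. t-1`), the percentage difference of the current week's value
#' from that average, and an indicator for the current value exceeding
#' it. Weeks 1-3 are flagged unavailable (`NA`).
#'
#' When the moving average is 0 and the current value is positive, the
#' percentage difference is undefined; it falls back to the current raw
#' value relative to a floor of one unit (with a warning), keeping the
#' feature finite and monotone. When both are 0 the difference is 0.
#'
#' @param values Numeric per-week series (weekly cases or case rates).
#' @param zero_ma_fallback Value used as denominator floor when the
#'   moving average is zero but the current value is positive; default 1.
#' @return Tibble with columns `ma`, `pct_diff`, `above` (0/1), one row
#'   per week; `pct_diff >= -1` wherever defined.
#' @export
three_week_ma_features <- function(values, zero_ma_fallback = 1) {
  n <- length(values)
  ma <- rep(NA_real_, n)
  if (n >= 4) {
    idx <- 4:n
    ma[idx] <- (values[idx - 1] + values[idx - 2] + values[idx - 3]) / 3
  }
  pct_diff <- rep(NA_real_, n)
  above <- rep(NA_real_, n)
  avail <- !is.na(ma)
  pos_ma <- avail & ma > 0
  pct_diff[pos_ma] <- (values[pos_ma] - ma[pos_ma]) / ma[pos_ma]
  zero_both <- avail & ma == 0 & values == 0
  pct_diff[zero_both] <- 0
  zero_ma <- avail & ma == 0 & values > 0
  if (any(zero_ma)) {
    warn("zero 3-week moving average with positive current value; using raw-value fallback for pct_diff")
    pct_diff[zero_ma] <- values[zero_ma] / zero_ma_fallback
  }
  above[avail] <- as.numeric(values[avail] > ma[avail])
  tibble(ma = ma, pct_diff = pct_diff, above = above)
}

#' Default temporal cut dates
#'
#' The second-wave onset and the late-December acceleration used by the
#' temporal indicator covariates.
#'
#' @return Named list with `wave2` and `dec25` dates.
#' @export
temporal_cuts <- function() {
  list(wave2 = as.Date("2020-10-30"), dec25 = as.Date("2020-12-25"))
}

#' Derive model covariates on a county-week panel
#'
#' Adds, per county, the log-rate outcomes, the case rate per 100
#' people with 1-3 week lags, the preceding-3-week moving-average
#' features of the case rate, log mobility exposure with 2-3 week lags,
#' temporal indicators at the configured cut dates, region dummies, and
#' logged static covariates.
#'
#' @param panel A `county_panel` (or a compatible frame that also
#'   carries extra, e.g. pre-sample, weeks).
#' @param cuts Temporal cut dates, see [temporal_cuts()].
#' @return The input with feature columns appended, ordered by county
#'   and week.
#' @export
add_panel_features <- function(panel, cuts = temporal_cuts()) {
  panel <- arrange(as_tibble(panel), .data$county_id, .data$week_index)
  panel <- panel |>
    mutate(
      ln_covid_hosp = log_rate(.data$covid_beds, .data$population),
      ln_noncovid_hosp = log_rate(.data$noncovid_beds, .data$population),
      ln_covid_icu = log_rate(.data$covid_icu, .data$population),
      ln_noncovid_icu = log_rate(.data$noncovid_icu, .data$population),
      case_rate = 100 * .data$weekly_cases / .data$population,
      ln_mob = log(.data$mobility_exposure),
      ln_median_income = log(.data$median_income),
      ln_cardio = log(.data$cardio_per_1000),
      ln_hiv = log(.data$hiv_rate_per_100k),
      ln_cancer = log(.data$cancer_rate_per_100k),
      since_wave2 = as.numeric(.data$week_end_date >= cuts$wave2),
      since_dec25 = as.numeric(.data$week_end_date >= cuts$dec25),
      region_west = as.numeric(.data$region == "West"),
      region_midwest = as.numeric(.data$region == "MidWest"),
      region_northeast = as.numeric(.data$region == "NorthEast"),
      region_south = as.numeric(.data$region == "South")
    )
  by_county <- panel |>
    group_by(.data$county_id) |>
    group_modify(function(df, key) {
      wma <- three_week_ma_features(df$case_rate)
      df$case_lag1 <- lagged_series(df$case_rate, 1)
      df$case_lag2 <- lagged_series(df$case_rate, 2)
      df$case_lag3 <- lagged_series(df$case_rate, 3)
      df$wma_3 <- wma$ma
      df$wma_pct_diff <- wma$pct_diff
      df$wma_above <- wma$above
      df$ln_mob_lag2 <- lagged_series(df$ln_mob, 2)
      df$ln_mob_lag3 <- lagged_series(df$ln_mob, 3)
      df
    }) |>
    ungroup()
  by_county
}
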