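#' Forecast county hospital demand under a scenario
#'
#' Rolls the feature pipeline forward week by week: each county's case
#' series is extended by its reference level times the scenario
#' multipliers, mobility is held at a fixed profile (the county mean of
#' its last three observed weeks), static covariates stay fixed, and
#' temporal indicators follow the forecast calendar. Predictions are
#' the marginal means `y_hat = X beta_hat` back-transformed to rates
#' per 100k (no residual carry-forward); an optional lognormal mean
#' correction `exp(sigma2/2)` is available but off by default.
#'
#' @param fits A fitted `arma_lmm`, or a (possibly named) list of fits
#'   for several outcomes.
#' @param panel The observed `county_panel`.
#' @param trajectory A [make_trajectory()] scenario.
#' @param horizon Forecast weeks `H` (default: the trajectory length).
#'   `H = 0` returns in-sample fitted values for the final observed
#'   week.
#' @param start_date Week-end date label of forecast week 1 (default
#'   2021-03-05, the study's projection calendar).
#' @param mobility_weeks Trailing observed weeks averaged for the held
#'   mobility profile.
#' @param lognormal_correction Multiply the back-transformed mean by
#'   `exp(sigma2 / 2)` before subtracting 1.
#' @return Tibble with one row per county, forecast week and outcome:
#'   `county_id`, `week`, `week_end_date`, `outcome`, `scenario`,
#'   `pred_log_rate`, `rate_per_100k`, `predicted_count` (rates and
#'   counts are nonnegative; counts are not capacity-capped so demand
#'   overruns remain visible).
#' @export
forecast_demand <- function(fits, panel, trajectory,
                            horizon = NULL,
                            start_date = as.Date("2021-03-05"),
                            mobility_weeks = 3,
                            lognormal_correction = FALSE) {
  if (inherits(fits, "arma_lmm")) fits <- list(fits)
  for (f in fits) {
    if (!inherits(f, "arma_lmm")) {
      stop_hospanel("fits must be arma_lmm objects",
                    class = "hospanel_state_error")
    }
    if (!isTRUE(f$converged)) {
      stop_hospanel("cannot forecast from a non-converged fit",
                    class = "hospanel_state_error")
    }
  }
  names(fits) <- vapply(fits, function(f) f$spec$outcome, "")
  horizon <- horizon %||% nrow(trajectory)
  if (horizon > nrow(trajectory)) {
    stop_hospanel("horizon exceeds trajectory length",
                  class = "hospanel_parameter_error")
  }

  panel <- as_tibble(panel)
  t_obs <- max(panel$week_index)

  if (horizon >= 1) {
    future_cases <- apply_scenario(panel, trajectory) |>
      filter(.data$week <= horizon)
    statics <- panel |>
      group_by(.data$county_id) |>
      arrange(.data$week_index, .by_group = TRUE) |>
      summarise(
        mobility_hold = exp(mean(tail(log(.data$mobility_exposure),
                                      mobility_weeks))),
        .groups = "drop"
      )
    county_static <- panel |>
      filter(.data$week_index == t_obs) |>
      select(-"week_index", -"week_end_date", -"weekly_cases",
             -"mobility_exposure")
    future <- future_cases |>
      left_join(statics, by = "county_id") |>
      left_join(county_static, by = "county_id") |>
      mutate(
        week_index = t_obs + .data$week,
        week_end_date = start_date + 7 * (.data$week - 1),
        mobility_exposure = .data$mobility_hold,
        covid_beds = 0, noncovid_beds = 0, covid_icu = 0, noncovid_icu = 0
      ) |>
      select(-"mobility_hold", -"week")
    extended <- bind_rows(
      panel |> select(all_of(panel_columns())),
      future |> select(all_of(panel_columns()))
    )
    target_weeks <- t_obs + seq_len(horizon)
  } else {
    extended <- panel |> select(all_of(panel_columns()))
    target_weeks <- t_obs
  }

  feats <- add_panel_features(extended)
  out <- list()
  for (o in names(fits)) {
    fit <- fits[[o]]
    d <- build_design(feats, fit$spec)
    rows <- d$index$week_index %in% target_weeks
    X <- d$X[rows, names(fit$beta), drop = FALSE]
    yhat <- drop(X %*% fit$beta)
    s2 <- fit$cov_params$sigma2
    rate <- if (lognormal_correction) {
      exp(yhat + s2 / 2) - 1
    } else {
      inv_log_rate(yhat)
    }
    rate <- pmax(rate, 0)
    idx <- d$index[rows, ]
    pop <- panel$population[match(idx$county_id, panel$county_id)]
    out[[o]] <- tibble(
      county_id = idx$county_id,
      week = idx$week_index - t_obs,
      week_end_date = idx$week_end_date,
      outcome = o,
      scenario = attr(trajectory, "kind"),
      pred_log_rate = yhat,
      rate_per_100k = rate,
      predicted_count = rate * pop / 1e5
    )
  }
  bind_rows(out) |>
    arrange(.data$county_id, .data$week, .data$outcome)
}
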