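# Exogenous COVID-transmission scenarios: per-week positive multipliers
# applied to each county's reference case rate over the forecast
# horizon.

scenario_kinds <- function() c("PV", "UP", "SB", "RV")

default_scenario_params <- function(kind) {
  switch(kind,
    # repetitive waves oscillating about the current level
    PV = list(amplitude = 0.35, period = 8),
    # ramp to an early-spring spike, then geometric decay
    UP = list(spike_week = 6, spike_gain = 2.5, decay = 0.85),
    # slow decline with a floor that is not reached until late summer
    SB = list(decay = 0.93, floor = 0.1),
    # fast decline to a manageable level by early summer
    RV = list(decay = 2^(-1 / 3))
  )
}

#' Build a scenario trajectory
#'
#' Deterministic per-week case-rate multipliers for one of the four
#' transmission scenarios:
#' * `PV` (peak and valley): `m(t) = 1 + a * sin(2 pi t / p)`.
#' * `UP` (unexpected spike): linear ramp to gain `g` at week `s`,
#'   then `m(t) = 1 + (g - 1) * d^(t - s)`.
#' * `SB` (slow burn): `m(t) = max(f, d^t)` with slow decay `d`.
#' * `RV` (rapid vaccination): `m(t) = d^t` with fast decay `d`.
#'
#' @param kind One of `"PV"`, `"UP"`, `"SB"`, `"RV"`.
#' @param params Named list of kind-specific shape parameters;
#'   defaults are used for any omitted entry.
#' @param horizon Number of forecast weeks `H >= 1` (default 22).
#' @return A `scenario_trajectory` tibble with columns `week` and
#'   `multiplier` (all positive), carrying `kind` and `params`
#'   attributes.
#' @export
make_trajectory <- function(kind, params = list(), horizon = 22) {
  kind <- match.arg(kind, scenario_kinds())
  if (horizon < 1) {
    stop_hospanel("horizon must be >= 1", class = "hospanel_parameter_error")
  }
  p <- utils::modifyList(default_scenario_params(kind), params)
  t <- seq_len(horizon)
  m <- switch(kind,
    PV = {
      if (p$amplitude >= 1 || p$amplitude < 0) {
        stop_hospanel("PV amplitude must lie in [0, 1)",
                      class = "hospanel_parameter_error")
      }
      1 + p$amplitude * sin(2 * pi * t / p$period)
    },
    UP = ifelse(t <= p$spike_week,
                1 + (p$spike_gain - 1) * t / p$spike_week,
                1 + (p$spike_gain - 1) * p$decay^(t - p$spike_week)),
    SB = pmax(p$floor, p$decay^t),
    RV = p$decay^t
  )
  if (any(m <= 0)) {
    stop_hospanel("scenario multipliers must be positive",
                  class = "hospanel_parameter_error")
  }
  structure(
    tibble(week = t, multiplier = m),
    kind = kind, params = p,
    class = c("scenario_trajectory", class(tibble()))
  )
}

#' @export
print.scenario_trajectory <- function(x, ...) {
  cat(sprintf("<scenario_trajectory> %s, horizon %d\n",
              attr(x, "kind"), nrow(x)))
  NextMethod()
}

#' Plot scenario multipliers
#'
#' @param object A `scenario_trajectory` (or list of them).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_trajectory
#' @export
autoplot.scenario_trajectory <- function(object, ...) {
  df <- mutate(as_tibble(object), scenario = attr(object, "kind"))
  ggplot2::ggplot(df, ggplot2::aes(.data$week, .data$multiplier)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "forecast week", y = "case-rate multiplier",
                  title = attr(object, "kind"))
}

#' Extend county case series under a scenario
#'
#' Each county's reference case level is the mean of its last three
#' observed weekly case counts; future week `t` carries
#' `reference * m(t)`, preserving the county-level spatial variability
#' of the observed panel.
#'
#' @param panel A `county_panel` with at least 3 observed weeks.
#' @param trajectory A [make_trajectory()] result.
#' @param reference_weeks Number of trailing observed weeks averaged
#'   for the reference level (default 3).
#' @return Tibble with `county_id`, `week` (1..H) and future
#'   `weekly_cases` (real-valued).
#' @export
apply_scenario <- function(panel, trajectory, reference_weeks = 3) {
  panel <- as_tibble(panel)
  n_obs <- length(unique(panel$week_index))
  if (n_obs < reference_weeks) {
    stop_hospanel("panel has fewer observed weeks than the reference window",
                  class = "hospanel_parameter_error")
  }
  ref <- panel |>
    group_by(.data$county_id) |>
    arrange(.data$week_index, .by_group = TRUE) |>
    summarise(reference = mean(tail(.data$weekly_cases, reference_weeks)),
              .groups = "drop")
  tidyr::crossing(ref, as_tibble(trajectory)) |>
    mutate(weekly_cases = .data$reference * .data$multiplier) |>
    select("county_id", "week", "weekly_cases") |>
    arrange(.data$county_id, .data$week)
}
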