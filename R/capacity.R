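# Occupancy and COVID-share stress metrics behind the capacity
# reporting: per-county flags at the >= 90% occupancy and >= 25%
# COVID-share thresholds, aggregated by pooling counts (not averaging
# fractions) to state, regional or national resolution.

#' Stress thresholds
#'
#' @param occupancy Occupancy stress threshold (fraction of capacity
#'   in use; inclusive). Default 0.90.
#' @param covid_share COVID-share stress threshold (fraction of
#'   occupied beds/ICU that are COVID; inclusive). Default 0.25.
#' @return Named list of thresholds.
#' @export
stress_thresholds <- function(occupancy = 0.90, covid_share = 0.25) {
  list(occupancy = occupancy, covid_share = covid_share)
}

#' Per-county-week occupancy and COVID-share metrics
#'
#' From a forecast (or any long table of the four outcome counts),
#' computes bed and ICU occupancy (`occupied / capacity`), the COVID
#' share of occupied beds/ICU (0 when nothing is occupied), and the
#' four inclusive stress flags. Counties with zero capacity are
#' excluded with a warning.
#'
#' @param forecast Long tibble as returned by [forecast_demand()]
#'   (columns `county_id`, `week`, `outcome`, `predicted_count`), or a
#'   `county_panel` (observed counts are used).
#' @param capacities Per-county capacities from [county_capacities()].
#' @param thresholds A [stress_thresholds()] list.
#' @return Tibble with one row per county-week: occupancies, shares,
#'   flags, and the spatial identifiers from `capacities`.
#' @export
occupancy_metrics <- function(forecast, capacities,
                              thresholds = stress_thresholds()) {
  if (inherits(forecast, "county_panel") ||
      all(c("covid_beds", "noncovid_beds") %in% names(forecast))) {
    wide <- as_tibble(forecast) |>
      select("county_id", week = "week_index", "covid_beds",
             "noncovid_beds", "covid_icu", "noncovid_icu")
  } else {
    wide <- forecast |>
      select("county_id", "week", "outcome", "predicted_count") |>
      tidyr::pivot_wider(names_from = "outcome",
                         values_from = "predicted_count") |>
      rename(covid_beds = "ln_covid_hosp", noncovid_beds = "ln_noncovid_hosp",
             covid_icu = "ln_covid_icu", noncovid_icu = "ln_noncovid_icu")
  }
  bad_cap <- capacities |>
    filter(.data$bed_capacity <= 0 | .data$icu_capacity <= 0)
  if (nrow(bad_cap) > 0) {
    warn(paste0("excluding ", nrow(bad_cap),
                " county(ies) with zero capacity"))
    capacities <- anti_join(capacities, bad_cap, by = "county_id")
  }
  wide |>
    inner_join(capacities, by = "county_id") |>
    mutate(
      bed_occupancy = (.data$covid_beds + .data$noncovid_beds) /
        .data$bed_capacity,
      icu_occupancy = (.data$covid_icu + .data$noncovid_icu) /
        .data$icu_capacity,
      covid_bed_share = ifelse(.data$covid_beds + .data$noncovid_beds > 0,
                               .data$covid_beds /
                                 (.data$covid_beds + .data$noncovid_beds), 0),
      covid_icu_share = ifelse(.data$covid_icu + .data$noncovid_icu > 0,
                               .data$covid_icu /
                                 (.data$covid_icu + .data$noncovid_icu), 0),
      over_90_beds = .data$bed_occupancy >= thresholds$occupancy,
      over_90_icu = .data$icu_occupancy >= thresholds$occupancy,
      covid_share_25_beds = .data$covid_bed_share >= thresholds$covid_share,
      covid_share_25_icu = .data$covid_icu_share >= thresholds$covid_share
    )
}

#' Aggregate capacity metrics to a spatial resolution
#'
#' Counts and capacities are pooled within each unit before occupancy
#' and share are recomputed (a capacity-weighted rollup, not an
#' average of fractions); flag columns become the fraction of member
#' counties carrying the flag.
#'
#' @param metrics Output of [occupancy_metrics()].
#' @param level `"county"`, `"state"`, `"region"` or `"national"`.
#' @return Tibble with one row per spatial unit and week.
#' @export
aggregate_capacity <- function(metrics,
                               level = c("county", "state", "region",
                                         "national")) {
  level <- match.arg(level)
  if (level == "county") {
    return(mutate(metrics, unit = .data$county_id, .before = 1))
  }
  metrics <- metrics |>
    mutate(unit = switch(level,
                         state = .data$state_code,
                         region = .data$region,
                         national = "US"))
  if (any(is.na(metrics$unit))) {
    missing <- unique(metrics$county_id[is.na(metrics$unit)])
    stop_hospanel(
      paste0("county(ies) missing from the spatial mapping: ",
             paste(head(missing, 10), collapse = ", ")),
      class = "hospanel_mapping_error"
    )
  }
  metrics |>
    group_by(.data$unit, .data$week) |>
    summarise(
      n_counties = n(),
      covid_beds = sum(.data$covid_beds),
      noncovid_beds = sum(.data$noncovid_beds),
      covid_icu = sum(.data$covid_icu),
      noncovid_icu = sum(.data$noncovid_icu),
      bed_capacity = sum(.data$bed_capacity),
      icu_capacity = sum(.data$icu_capacity),
      frac_over_90_beds = mean(.data$over_90_beds),
      frac_over_90_icu = mean(.data$over_90_icu),
      frac_covid_share_25_beds = mean(.data$covid_share_25_beds),
      frac_covid_share_25_icu = mean(.data$covid_share_25_icu),
      .groups = "drop"
    ) |>
    mutate(
      bed_occupancy = (.data$covid_beds + .data$noncovid_beds) /
        .data$bed_capacity,
      icu_occupancy = (.data$covid_icu + .data$noncovid_icu) /
        .data$icu_capacity,
      covid_bed_share = ifelse(.data$covid_beds + .data$noncovid_beds > 0,
                               .data$covid_beds /
                                 (.data$covid_beds + .data$noncovid_beds), 0),
      covid_icu_share = ifelse(.data$covid_icu + .data$noncovid_icu > 0,
                               .data$covid_icu /
                                 (.data$covid_icu + .data$noncovid_icu), 0)
    )
}

#' Cross-scenario stress comparison
#'
#' For each scenario and week, the fraction of counties over each
#' stress threshold. All scenarios must cover the same county set.
#'
#' @param metrics_by_scenario Named list of county-level
#'   [occupancy_metrics()] outputs, one per scenario.
#' @return Tibble sorted by scenario then week with the four flagged
#'   fractions.
#' @export
stress_table <- function(metrics_by_scenario) {
  county_sets <- lapply(metrics_by_scenario,
                        function(m) sort(unique(m$county_id)))
  if (length(unique(county_sets)) != 1) {
    stop_hospanel("scenarios cover different county sets",
                  class = "hospanel_mapping_error")
  }
  purrr::imap(metrics_by_scenario, function(m, nm) {
    m |>
      group_by(.data$week) |>
      summarise(
        n_counties = n(),
        frac_over_90_beds = mean(.data$over_90_beds),
        frac_over_90_icu = mean(.data$over_90_icu),
        frac_covid_share_25_beds = mean(.data$covid_share_25_beds),
        frac_covid_share_25_icu = mean(.data$covid_share_25_icu),
        .groups = "drop"
      ) |>
      mutate(scenario = nm, .before = 1)
  }) |>
    bind_rows() |>
    arrange(.data$scenario, .data$week)
}

#' Occupancy-over-time plot
#'
#' Line plot of pooled occupancy by week, one line per scenario,
#' faceted by spatial unit.
#'
#' @param summaries Named list (by scenario) of [aggregate_capacity()]
#'   outputs, or a single combined tibble with a `scenario` column.
#' @param what `"beds"` or `"icu"`.
#' @param threshold Reference line (default 0.9).
#' @return A ggplot object.
#' @export
plot_occupancy <- function(summaries, what = c("beds", "icu"),
                           threshold = 0.9) {
  what <- match.arg(what)
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- bind_rows(purrr::imap(
      summaries, function(s, nm) mutate(s, scenario = nm)
    ))
  }
  ycol <- if (what == "beds") "bed_occupancy" else "icu_occupancy"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$week, .data[[ycol]],
                               colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit) +
    ggplot2::labs(x = "forecast week",
                  y = paste(what, "occupancy (fraction of capacity)"),
                  colour = "scenario")
}

#' Stress-fraction bar plot
#'
#' Fractions of counties over each stress threshold by scenario and
#' week.
#'
#' @param stress A [stress_table()] result.
#' @return A ggplot object.
#' @export
plot_stress <- function(stress) {
  long <- stress |>
    tidyr::pivot_longer(starts_with("frac_"), names_to = "measure",
                        values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$fraction,
                                     fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "forecast week", y = "fraction of counties")
}
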