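#' County-week panel columns
#'
#' Column names required of a county-week panel: identifiers, the four
#' weekly outcome counts (COVID / non-COVID hospital beds and ICU beds in
#' use), capacities, weekly COVID cases, the daily-average mobility
#' exposure, and static county covariates (demographics, health
#' indicators, spatial factors).
#'
#' @return Character vector of required column names.
#' @export
panel_columns <- function() {
  c(
    "county_id", "state_code", "region", "week_index", "week_end_date",
    "population",
    "covid_beds", "noncovid_beds", "covid_icu", "noncovid_icu",
    "bed_capacity", "icu_capacity",
    "weekly_cases", "mobility_exposure",
    "young_pct", "hispanic_pct", "african_american_pct", "female_pct",
    "median_income",
    "cardio_per_1000", "hepc_per_100k", "hiv_rate_per_100k",
    "cancer_rate_per_100k",
    "top10_tourist", "airports_per_100k"
  )
}

#' Census-style region levels
#'
#' @return Character vector of the four region levels.
#' @export
region_levels <- function() c("West", "MidWest", "NorthEast", "South")

panel_count_columns <- function() {
  c("covid_beds", "noncovid_beds", "covid_icu", "noncovid_icu",
    "weekly_cases")
}

#' Validate a county-week panel
#'
#' Checks the schema, the balance of the panel (every county observed at
#' the same consecutive weeks), nonnegativity and integrality of counts,
#' percentage ranges, and the capacity bounds
#' `covid_beds + noncovid_beds <= bed_capacity` (likewise for ICU).
#'
#' @param panel A data frame with the columns of [panel_columns()].
#' @param drop_incomplete If `TRUE`, counties without the full set of
#'   weeks are dropped (with a warning) instead of raising a balance
#'   error.
#' @return The validated panel as a tibble, invisibly classed
#'   `county_panel`.
#' @export
as_county_panel <- function(panel, drop_incomplete = FALSE) {
  panel <- as_tibble(panel)
  missing_cols <- setdiff(panel_columns(), names(panel))
  if (length(missing_cols) > 0) {
    stop_hospanel(
      paste0("panel is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "hospanel_schema_error"
    )
  }
  panel$week_end_date <- as.Date(panel$week_end_date)
  if (any(abs(panel$week_index - round(panel$week_index)) > 1e-8)) {
    stop_hospanel("week_index must be integer-valued",
                  class = "hospanel_schema_error")
  }
  panel$week_index <- as.integer(round(panel$week_index))
  bad_region <- setdiff(unique(panel$region), region_levels())
  if (length(bad_region) > 0) {
    stop_hospanel(
      paste0("unknown region level(s): ", paste(bad_region, collapse = ", ")),
      class = "hospanel_schema_error"
    )
  }

  weeks <- sort(unique(panel$week_index))
  if (!identical(weeks, seq(min(weeks), max(weeks)))) {
    stop_hospanel("week_index values must be consecutive integers",
                  class = "hospanel_balance_error")
  }
  tab <- panel |>
    count(.data$county_id, name = "n_weeks")
  incomplete <- tab$county_id[tab$n_weeks != length(weeks)]
  dup <- panel |>
    count(.data$county_id, .data$week_index) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_hospanel("panel has duplicated county-week records",
                  class = "hospanel_balance_error")
  }
  if (length(incomplete) > 0) {
    if (drop_incomplete) {
      warn(paste0("dropping ", length(incomplete),
                  " incomplete county(ies): ",
                  paste(head(incomplete, 5), collapse = ", "),
                  if (length(incomplete) > 5) ", ..." else ""))
      panel <- filter(panel, !.data$county_id %in% incomplete)
    } else {
      stop_hospanel(
        paste0("unbalanced panel; county(ies) without all ", length(weeks),
               " weeks: ", paste(head(incomplete, 10), collapse = ", "),
               if (length(incomplete) > 10) ", ..." else ""),
        class = "hospanel_balance_error"
      )
    }
  }

  for (col in panel_count_columns()) {
    x <- panel[[col]]
    if (any(x < 0, na.rm = TRUE)) {
      stop_hospanel(paste0("negative values in count column ", col),
                    class = "hospanel_validation_error")
    }
    if (any(abs(x - round(x)) > 1e-8, na.rm = TRUE)) {
      stop_hospanel(paste0("non-integer values in count column ", col),
                    class = "hospanel_validation_error")
    }
  }
  if (any(panel$population <= 0)) {
    stop_hospanel("population must be positive",
                  class = "hospanel_validation_error")
  }
  if (any(panel$bed_capacity <= 0) || any(panel$icu_capacity <= 0)) {
    stop_hospanel("capacities must be positive",
                  class = "hospanel_validation_error")
  }
  over_beds <- panel$covid_beds + panel$noncovid_beds > panel$bed_capacity
  over_icu <- panel$covid_icu + panel$noncovid_icu > panel$icu_capacity
  if (any(over_beds) || any(over_icu)) {
    stop_hospanel("occupied beds/ICU exceed capacity for some county-weeks",
                  class = "hospanel_validation_error")
  }
  pct_cols <- c("young_pct", "hispanic_pct", "african_american_pct",
                "female_pct")
  for (col in pct_cols) {
    if (any(panel[[col]] < 0 | panel[[col]] > 100)) {
      stop_hospanel(paste0(col, " outside [0, 100]"),
                    class = "hospanel_validation_error")
    }
  }

  panel <- arrange(panel, .data$county_id, .data$week_index)
  class(panel) <- unique(c("county_panel", class(panel)))
  panel
}

#' Read a county-week panel from CSV
#'
#' One row per county-week, ISO-8601 dates, empty cells for missing
#' values. The file is validated with [as_county_panel()].
#'
#' @param path Path to a CSV file.
#' @param drop_incomplete Drop counties missing some weeks instead of
#'   erroring.
#' @return A validated `county_panel` tibble.
#' @export
read_panel <- function(path, drop_incomplete = FALSE) {
  if (!file.exists(path)) {
    stop_hospanel(paste0("no such file: ", path), class = "hospanel_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_county_panel(raw, drop_incomplete = drop_incomplete)
}

#' Write a county-week panel to CSV
#'
#' @param panel A `county_panel` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_county_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Static per-county capacities
#'
#' Extracts one row per county with its population, capacities and
#' spatial identifiers, for use by the capacity reporting functions.
#'
#' @param panel A `county_panel`.
#' @return Tibble with one row per county.
#' @export
county_capacities <- function(panel) {
  panel |>
    group_by(.data$county_id) |>
    summarise(
      state_code = first(.data$state_code),
      region = first(.data$region),
      population = first(.data$population),
      bed_capacity = first(.data$bed_capacity),
      icu_capacity = first(.data$icu_capacity),
      .groups = "drop"
    )
}
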