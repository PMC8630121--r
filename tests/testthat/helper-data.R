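# Small deterministic panels for unit tests.

# Hand-built valid panel: `n` counties x `T` weeks, simple increasing
# case counts, generous capacities.
tiny_panel <- function(n_counties = 3, n_weeks = 6) {
  grid <- expand.grid(
    week_index = seq_len(n_weeks),
    county_id = sprintf("C%02d", seq_len(n_counties)),
    stringsAsFactors = FALSE
  )
  regions <- rep(c("South", "West", "MidWest", "NorthEast"),
                 length.out = n_counties)
  tibble::tibble(
    county_id = grid$county_id,
    state_code = rep(c("TX", "CA", "OH", "NY"),
                     length.out = n_counties)[match(grid$county_id,
                                                    unique(grid$county_id))],
    region = regions[match(grid$county_id, unique(grid$county_id))],
    week_index = grid$week_index,
    week_end_date = as.Date("2020-08-28") + 7 * (grid$week_index - 1),
    population = 1e5,
    covid_beds = 10 + grid$week_index,
    noncovid_beds = 50,
    covid_icu = 2,
    noncovid_icu = 5,
    bed_capacity = 500,
    icu_capacity = 50,
    weekly_cases = 100 * grid$week_index,
    mobility_exposure = 90,
    young_pct = 22, hispanic_pct = 10, african_american_pct = 9,
    female_pct = 50, median_income = 52000,
    cardio_per_1000 = 60, hepc_per_100k = 1,
    hiv_rate_per_100k = 120, cancer_rate_per_100k = 450,
    top10_tourist = 0, airports_per_100k = 1.2
  )
}

# Generated small panel (cached per seed within a test run).
small_panel_cache <- new.env(parent = emptyenv())
small_generated_panel <- function(n_counties = 60, n_weeks = 14, seed = 11) {
  key <- paste(n_counties, n_weeks, seed, sep = "_")
  if (is.null(small_panel_cache[[key]])) {
    # start so that both temporal cut dates fall inside short windows
    start <- if (n_weeks < 21) as.Date("2020-10-02") else
      as.Date("2020-08-28")
    cfg <- generator_config(n_counties = n_counties, n_weeks = n_weeks,
                            seed = seed, start_date = start)
    small_panel_cache[[key]] <- generate_panel(cfg)
  }
  small_panel_cache[[key]]
}

# Full study-scale panel, generated once and shared by the acceptance
# tests.
study_panel_cache <- new.env(parent = emptyenv())
study_panel <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(study_panel_cache[[key]])) {
    study_panel_cache[[key]] <- generate_panel(generator_config(seed = seed))
  }
  study_panel_cache[[key]]
}
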