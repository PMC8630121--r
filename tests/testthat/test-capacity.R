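make_metrics_frame <- function(covid, noncovid, capacity,
                               covid_icu = 0, noncovid_icu = 0,
                               icu_capacity = 10) {
  n <- length(covid)
  forecast <- tibble::tibble(
    county_id = rep(sprintf("C%02d", seq_len(n)), times = 4),
    week = 1,
    outcome = rep(c("ln_covid_hosp", "ln_noncovid_hosp",
                    "ln_covid_icu", "ln_noncovid_icu"), each = n),
    predicted_count = c(covid, noncovid, rep(covid_icu, n),
                        rep(noncovid_icu, n))
  )
  capacities <- tibble::tibble(
    county_id = sprintf("C%02d", seq_len(n)),
    state_code = "TX", region = "South", population = 1e5,
    bed_capacity = capacity, icu_capacity = icu_capacity
  )
  list(forecast = forecast, capacities = capacities)
}

test_that("occupancy and COVID share match hand calculations", {
  m <- make_metrics_frame(covid = 30, noncovid = 50, capacity = 100)
  out <- occupancy_metrics(m$forecast, m$capacities)
  expect_equal(out$bed_occupancy, 0.80)
  expect_equal(out$covid_bed_share, 0.375)
  expect_false(out$over_90_beds)

  empty <- make_metrics_frame(covid = 0, noncovid = 0, capacity = 100)
  out0 <- occupancy_metrics(empty$forecast, empty$capacities)
  expect_equal(out0$bed_occupancy, 0)
  expect_equal(out0$covid_bed_share, 0)
  expect_false(any(out0$over_90_beds, out0$covid_share_25_beds))

  # thresholds are inclusive ("at least")
  exact <- make_metrics_frame(covid = 25, noncovid = 65, capacity = 100)
  oute <- occupancy_metrics(exact$forecast, exact$capacities)
  expect_true(oute$over_90_beds)
  expect_true(oute$covid_share_25_beds)
})

test_that("zero-capacity counties are excluded with a warning", {
  m <- make_metrics_frame(covid = c(10, 10), noncovid = c(10, 10),
                          capacity = c(100, 0))
  expect_warning(out <- occupancy_metrics(m$forecast, m$capacities),
                 "zero capacity")
  expect_identical(nrow(out), 1L)
})

test_that("aggregation pools counts before recomputing ratios", {
  m <- make_metrics_frame(covid = c(20, 80), noncovid = c(30, 20),
                          capacity = c(100, 100))
  metrics <- occupancy_metrics(m$forecast, m$capacities)
  # occupancies 0.5 and 1.0 with equal capacity pool to 0.75
  agg <- aggregate_capacity(metrics, "region")
  expect_equal(agg$bed_occupancy, 0.75)
  expect_equal(agg$frac_over_90_beds, 0.5)

  # a single-county unit reproduces the county metrics
  single <- aggregate_capacity(metrics[metrics$county_id == "C01", ],
                               "national")
  expect_equal(single$bed_occupancy, metrics$bed_occupancy[1])
  expect_equal(single$covid_bed_share, metrics$covid_bed_share[1])
})

test_that("pooled occupancy equals the capacity-weighted county mean", {
  p <- small_generated_panel(n_counties = 25, n_weeks = 8, seed = 19)
  metrics <- occupancy_metrics(p, county_capacities(p))
  nat <- aggregate_capacity(metrics, "national")
  weighted <- metrics |>
    dplyr::group_by(week) |>
    dplyr::summarise(w = sum(bed_occupancy * bed_capacity) /
                       sum(bed_capacity))
  expect_equal(nat$bed_occupancy, weighted$w, tolerance = 1e-12)
})

test_that("raising a threshold never increases the flagged fraction", {
  p <- small_generated_panel(n_counties = 25, n_weeks = 8, seed = 19)
  caps <- county_capacities(p)
  fracs <- vapply(c(0.01, 0.02, 0.05, 0.5, 0.9), function(th) {
    m <- occupancy_metrics(p, caps, stress_thresholds(occupancy = th))
    mean(m$over_90_beds)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("stress tables compare scenarios consistently", {
  m <- make_metrics_frame(covid = c(20, 95), noncovid = c(30, 4),
                          capacity = c(100, 100))
  metrics <- occupancy_metrics(m$forecast, m$capacities)
  st <- stress_table(list(PV = metrics, RV = metrics))
  expect_identical(nrow(st), 2L)
  expect_equal(st$frac_over_90_beds[1], st$frac_over_90_beds[2])
  expect_equal(st$frac_over_90_beds[1], 0.5)

  other <- metrics[metrics$county_id == "C01", ]
  expect_error(stress_table(list(PV = metrics, RV = other)),
               class = "hospanel_mapping_error")

  low <- make_metrics_frame(covid = c(1, 1), noncovid = c(1, 1),
                            capacity = c(100, 100))
  lowm <- occupancy_metrics(low$forecast, low$capacities)
  st0 <- stress_table(list(PV = lowm))
  expect_true(all(st0$frac_over_90_beds == 0, st0$frac_over_90_icu == 0))
})

test_that("aggregation errors when the spatial mapping is incomplete", {
  m <- make_metrics_frame(covid = c(10, 10), noncovid = c(10, 10),
                          capacity = c(100, 100))
  caps <- m$capacities
  caps$region[2] <- NA
  metrics <- occupancy_metrics(m$forecast, caps)
  expect_error(aggregate_capacity(metrics, "region"), "C02",
               class = "hospanel_mapping_error")
})
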