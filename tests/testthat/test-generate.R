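test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_counties = 20, n_weeks = 8, seed = 9)
  c1 <- generate_counties(cfg)
  c2 <- generate_counties(cfg)
  expect_identical(c1, c2)
  d1 <- generate_dynamics(c1, cfg)
  d2 <- generate_dynamics(c1, cfg)
  expect_identical(d1, d2)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("county covariates respect the configured ranges", {
  cfg <- generator_config(n_counties = 300, n_weeks = 8, seed = 12)
  counties <- generate_counties(cfg)
  expect_true(all(counties$young_pct >= 7.155 &
                    counties$young_pct <= 35.987))
  expect_true(all(counties$female_pct >= 37.041 &
                    counties$female_pct <= 56.145))
  expect_true(all(log(counties$median_income) >= 10.149 &
                    log(counties$median_income) <= 11.821))
  expect_true(all(counties$top10_tourist %in% c(0, 1)))
  expect_setequal(unique(counties$region), region_levels())
})

test_that("collapsed covariate ranges give constant covariates", {
  rng <- covariate_range_defaults()
  rng$min <- rng$max <- rng$mean
  cfg <- generator_config(n_counties = 15, n_weeks = 8, seed = 2,
                          covariate_ranges = rng)
  counties <- generate_counties(cfg)
  expect_identical(length(unique(counties$young_pct)), 1L)
  expect_identical(length(unique(counties$hepc_per_100k)), 1L)
})

test_that("log mobility stays inside the published envelope", {
  cfg <- generator_config(n_counties = 120, n_weeks = 21, seed = 13)
  p <- generate_panel(cfg)
  lm_ <- log(p$mobility_exposure)
  expect_true(all(lm_ >= 2.319 & lm_ <= 6.841))
})

test_that("zero wave amplitude and zero noise give a flat case series", {
  cp <- generator_config()$case_process
  cp$wave1_amp <- cp$wave2_amp <- 0
  cp$noise_sd <- 0
  cp$county_sdlog <- 0
  cfg <- generator_config(n_counties = 5, n_weeks = 8, seed = 1,
                          case_process = cp)
  dyn <- generate_dynamics(generate_counties(cfg), cfg)
  rates <- dyn |>
    dplyr::left_join(generate_counties(cfg)[, c("county_id", "population")],
                     by = "county_id") |>
    dplyr::mutate(rate = 100 * weekly_cases / population)
  per_county_spread <- tapply(rates$rate, rates$county_id,
                              function(x) diff(range(x)))
  # constant up to count rounding
  expect_true(all(per_county_spread < 0.01))
  expect_equal(mean(rates$rate), cp$baseline, tolerance = 0.01)
})

test_that("simulated outcomes collapse to the mean in the no-noise limit", {
  withr::with_seed(4, {
    Z <- 6; Tn <- 5
    county <- rep(sprintf("C%02d", 1:Z), each = Tn)
    X <- cbind("(Intercept)" = 1, x = rnorm(Z * Tn))
    beta <- c("(Intercept)" = 2, x = -1)
    sim <- simulate_outcomes(X, county, beta, cov_params(1e-12, 0.8, 0.9),
                             seed = 5)
    expect_equal(sim$y, drop(X %*% beta), tolerance = 1e-4)
    sim1 <- simulate_outcomes(X, county, beta, cov_params(1.5, 0.8, 0.9),
                              seed = 6)
    sim2 <- simulate_outcomes(X, county, beta, cov_params(1.5, 0.8, 0.9),
                              seed = 6)
    expect_identical(sim1$y, sim2$y)
  })
})

test_that("simulated errors reproduce the target covariance empirically", {
  Z <- 4000; Tn <- 3
  county <- rep(sprintf("C%05d", 1:Z), each = Tn)
  X <- matrix(1, Z * Tn, 1, dimnames = list(NULL, "(Intercept)"))
  params <- cov_params(1.912, 0.835, 0.930)
  sim <- simulate_outcomes(X, county, c("(Intercept)" = 0), params,
                           seed = 314)
  E <- matrix(sim$eps, nrow = Tn)
  emp <- tcrossprod(E - rowMeans(E)) / (Z - 1)
  Om <- build_omega(params, Tn)
  mc_se <- sqrt((diag(Om) %o% diag(Om) + Om^2) / Z)
  expect_true(all(abs(emp - Om) < 3 * mc_se))
  expect_lt(max(abs(rowMeans(E))), 3 * sqrt(params$sigma2 / Z))
})

test_that("generated panels validate, round-trip, and carry their truth", {
  p <- small_generated_panel(n_counties = 30, n_weeks = 10, seed = 8)
  expect_s3_class(p, "county_panel")
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  p2 <- read_panel(path)
  expect_identical(nrow(p2), 300L)
  truth <- attr(p, "truth")
  expect_equal(truth$beta$ln_covid_hosp[["case_lag2"]], 1.266)
  expect_equal(truth$cov$ln_noncovid_hosp$rho, 0.965)
  clip <- attr(p, "clip_log")
  expect_true(all(clip$capacity <= 0.01 * nrow(p)))
})

test_that("generator configs round-trip through YAML", {
  cfg <- generator_config(n_counties = 25, n_weeks = 9, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_identical(cfg2$n_counties, 25L)
  expect_identical(cfg2$seed, 77L)
  expect_equal(cfg2$truth_beta$ln_covid_hosp, cfg$truth_beta$ln_covid_hosp)
  expect_equal(cfg2$truth_cov$ln_covid_hosp$rho, 0.930)
  expect_identical(as.data.frame(generate_panel(cfg2)),
                   as.data.frame(generate_panel(cfg)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_counties = 1),
               class = "hospanel_config_error")
  expect_error(generator_config(n_weeks = 4),
               class = "hospanel_config_error")
  rng <- covariate_range_defaults()
  rng$mean[1] <- rng$max[1] + 1
  expect_error(generator_config(covariate_ranges = rng),
               class = "hospanel_config_error")
})
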