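test_that("GLS reduces to OLS under independent errors", {
  y <- c(1, 2)
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  county <- c("A", "A")
  g <- gls_beta(y, X, county, cov_params(1, 0, 0))
  expect_equal(unname(g$beta), 1.5)
  expect_equal(unname(g$beta_cov[1, 1]), 0.5)
})

test_that("GLS interpolates noise-free data exactly for any covariance", {
  withr::with_seed(3, {
    Z <- 5; Tn <- 4
    county <- rep(letters[1:Z], each = Tn)
    X <- cbind("(Intercept)" = 1, x1 = rnorm(Z * Tn), x2 = rnorm(Z * Tn))
    beta0 <- c(2, -1, 0.5)
    y <- drop(X %*% beta0)
    for (params in list(cov_params(1.9, 0.835, 0.93),
                        cov_params(0.5, 0.3, -0.4))) {
      g <- gls_beta(y, X, county, params)
      expect_equal(unname(g$beta), beta0, tolerance = 1e-9)
    }
  })
})

test_that("GLS and the REML value are invariant to county reordering", {
  withr::with_seed(8, {
    inst <- random_instance(6, 4)
    blocks <- split(seq_along(inst$y), inst$county)
    perm <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
    g1 <- gls_beta(inst$y, inst$X, inst$county, inst$params)
    g2 <- gls_beta(inst$y[perm], inst$X[perm, ], inst$county[perm],
                   inst$params)
    expect_equal(g1$beta, g2$beta, tolerance = 1e-10)
    l1 <- reml_loglik(inst$y, inst$X, inst$county, inst$params)
    l2 <- reml_loglik(inst$y[perm], inst$X[perm, ], inst$county[perm],
                      inst$params)
    expect_equal(l1, l2, tolerance = 1e-10)
  })
})

test_that("REML log-likelihood matches the closed form on a tiny case", {
  # one county, two weeks, zero outcome, intercept only, identity Omega:
  # -(1/2) * [ln 2pi + ln 2] = -(1/2) ln 4pi
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  ll <- reml_loglik(c(0, 0), X, c("A", "A"), cov_params(1, 0, 0))
  expect_equal(ll, -0.5 * log(4 * pi), tolerance = 1e-12)
  expect_equal(ll, -1.2655, tolerance = 1e-4)
})

test_that("rank-deficient designs raise a singular-design error", {
  y <- rnorm(8)
  X <- cbind("(Intercept)" = rep(1, 8), dup = rep(1, 8))
  county <- rep(c("A", "B"), each = 4)
  expect_error(gls_beta(y, X, county, cov_params(1, 0.2, 0.5)),
               "dup", class = "hospanel_singular_error")
})

test_that("profiled REML equals the dense brute-force oracle", {
  withr::with_seed(101, {
    for (i in 1:12) {
      inst <- random_instance(sample(2:6, 1), sample(2:5, 1))
      expect_equal(
        reml_loglik(inst$y, inst$X, inst$county, inst$params),
        oracle_reml_loglik(inst$y, inst$X, inst$county, inst$params),
        tolerance = 1e-8
      )
    }
  })
})

test_that("fitting with phi fixed at 0 reproduces the independent-error fit", {
  p <- small_generated_panel(n_counties = 40, n_weeks = 14, seed = 6)
  spec <- spec_noncovid_hosp()
  fit <- fit_reml(p, spec, reml_control(fix = list(phi = 0, rho = 0)))
  d <- build_design(p, spec)
  lmfit <- stats::lm(d$y ~ d$X - 1)
  expect_equal(unname(fit$beta), unname(coef(lmfit)), tolerance = 1e-6)
  expect_equal(fit$cov_params$sigma2, summary(lmfit)$sigma^2,
               tolerance = 1e-6)
})

test_that("REML recovers independence when the truth has no correlation", {
  cfg <- generator_config(
    n_counties = 500, n_weeks = 21, seed = 17,
    truth_cov = lapply(truth_cov_defaults(), function(p) {
      cov_params(p$sigma2, 0, 0)
    })
  )
  p <- generate_panel(cfg)
  fit <- fit_reml(p, spec_covid_hosp())
  expect_true(fit$converged)
  # when the truth is independence, phi and rho are not separately
  # identified (the correlations phi * rho^k vanish for any phi when
  # rho = 0 and vice versa); the estimable lag-k correlations must all
  # come back near zero
  corr_hat <- fit$cov_params$phi * fit$cov_params$rho^(1:20)
  expect_lt(max(abs(corr_hat)), 0.02)
  truth_s2 <- truth_cov_defaults()$ln_covid_hosp$sigma2
  expect_lt(abs(fit$cov_params$sigma2 / truth_s2 - 1), 0.05)
})

test_that("the fitted parameters dominate the truth in REML value", {
  p <- small_generated_panel(n_counties = 80, n_weeks = 14, seed = 21)
  spec <- spec_noncovid_hosp()
  fit <- fit_reml(p, spec)
  d <- build_design(p, spec)
  ll_true <- reml_loglik(d$y, d$X, d$index$county_id,
                         truth_cov_defaults()$ln_noncovid_hosp)
  expect_gte(fit$reml_loglik, ll_true)
  # refitting the coefficients at the optimum changes nothing
  g <- gls_beta(d$y, d$X, d$index$county_id, fit$cov_params)
  expect_equal(g$beta, fit$beta, tolerance = 1e-10)
})

test_that("tidy and glance expose consistent inference", {
  p <- small_generated_panel(n_counties = 40, n_weeks = 14, seed = 6)
  fit <- fit_reml(p, spec_noncovid_hosp())
  td <- tidy(fit)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(td$statistic, td$estimate / td$std.error, tolerance = 1e-12)
  g <- glance(fit)
  expect_identical(g$nobs, fit$nobs)
  expect_true(g$converged)
})

test_that("fitted models serialize to JSON and back", {
  p <- small_generated_panel(n_counties = 40, n_weeks = 14, seed = 6)
  fit <- fit_reml(p, spec_noncovid_hosp())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  fit2 <- read_model(path)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
  expect_equal(fit2$cov_params$rho, fit$cov_params$rho, tolerance = 1e-12)
  expect_s3_class(fit2, "arma_lmm")
})
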