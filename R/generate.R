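# Synthetic county-week panel generator. Emulates the structure the
# analysis assumes: static county covariates within the published
# descriptive ranges, a two-wave weekly case process, a mobility
# exposure series with a late-December spike, and outcomes drawn from
# the panel model with ARMA-correlated errors at known ground truth.

#' Generator configuration
#'
#' @param n_counties Number of counties (study dimension: 1765).
#' @param n_weeks Number of observed weeks (study dimension: 21).
#' @param seed Integer seed; all draws are deterministic given it.
#' @param truth_beta Named list of coefficient vectors per outcome
#'   (defaults [truth_beta_defaults()]).
#' @param truth_cov Named list of [cov_params()] per outcome
#'   (defaults [truth_cov_defaults()]).
#' @param covariate_ranges Tibble of min/mean/max covariate ranges
#'   ([covariate_range_defaults()]).
#' @param region_probs Named region proportions (published dummy
#'   means; South is the remainder).
#' @param case_process Weekly case-rate process (per 100 people):
#'   baseline level, two Gaussian-shaped waves (amplitude, peak week,
#'   width) emulating the November and December surges, a county
#'   severity spread (`county_sdlog`), AR(1) multiplicative noise
#'   (`noise_sd`, `noise_ar`) and a hard cap `max_rate` at the
#'   published maximum.
#' @param mobility_process Log daily-average exposure envelope
#'   (published range), county-level mean spread, iid noise, and a
#'   late-December holiday spike (start week, gain).
#' @param capacity_process Log-normal beds and ICU-per-100k
#'   distributions (meanlog/sdlog) with absolute floors.
#' @param population_process Log-normal county population
#'   (meanlog/sdlog, min/max clamp).
#' @param start_date Week-end date of observed week 1.
#' @param burn_in Pre-sample weeks simulated so that lagged features
#'   exist for every observed week.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_counties = 1765,
                             n_weeks = 21,
                             seed = 20210122,
                             truth_beta = truth_beta_defaults(),
                             truth_cov = truth_cov_defaults(),
                             covariate_ranges = covariate_range_defaults(),
                             region_probs = c(West = 0.120, MidWest = 0.108,
                                              NorthEast = 0.308, South = 0.464),
                             case_process = list(
                               baseline = 1.9,
                               wave1_amp = 1.4, wave1_peak = 12, wave1_width = 3.2,
                               wave2_amp = 2.0, wave2_peak = 20, wave2_width = 4,
                               county_sdlog = 0.28,
                               noise_sd = 0.25, noise_ar = 0.6,
                               max_rate = 4.56
                             ),
                             mobility_process = list(
                               ln_min = 2.319, ln_max = 6.841, ln_mean = 4.536,
                               noise_sd = 0.06,
                               spike_week_offset = 4, spike_gain = 0.25
                             ),
                             capacity_process = list(
                               beds_meanlog = log(1300), beds_sdlog = 0.4,
                               icu_meanlog = log(110), icu_sdlog = 0.4,
                               beds_floor = 25, icu_floor = 4,
                               headroom_quantile = 2.9,
                               headroom_meanlog = log(1.15),
                               headroom_sdlog = 0.15
                             ),
                             population_process = list(
                               meanlog = log(110000), sdlog = 0.9,
                               min = 20000, max = 5e6
                             ),
                             start_date = as.Date("2020-08-28"),
                             burn_in = 3) {
  if (n_counties < 2) {
    stop_hospanel("n_counties must be >= 2", class = "hospanel_config_error")
  }
  if (n_weeks < 5) {
    stop_hospanel("n_weeks must be >= 5 (lags and moving averages need 4 prior weeks)",
                  class = "hospanel_config_error")
  }
  rng <- covariate_ranges
  if (any(rng$min > rng$mean | rng$mean > rng$max)) {
    stop_hospanel("covariate ranges must satisfy min <= mean <= max",
                  class = "hospanel_config_error")
  }
  structure(
    list(
      n_counties = as.integer(n_counties), n_weeks = as.integer(n_weeks),
      seed = as.integer(seed),
      truth_beta = truth_beta, truth_cov = truth_cov,
      covariate_ranges = covariate_ranges, region_probs = region_probs,
      case_process = case_process, mobility_process = mobility_process,
      capacity_process = capacity_process,
      population_process = population_process,
      start_date = as.Date(start_date), burn_in = as.integer(burn_in)
    ),
    class = "generator_config"
  )
}

region_state_pool <- function() {
  list(
    West = c("CA", "WA", "OR", "NV", "AZ", "CO", "UT", "NM", "ID", "MT", "WY"),
    MidWest = c("IL", "OH", "MI", "IN", "WI", "MN", "IA", "MO", "KS", "NE",
                "ND", "SD"),
    NorthEast = c("NY", "PA", "NJ", "MA", "CT", "RI", "VT", "NH", "ME"),
    South = c("TX", "FL", "GA", "NC", "VA", "TN", "AL", "SC", "LA", "KY",
              "OK", "AR", "MS", "WV", "MD", "DE")
  )
}

# Draw n values from a scaled beta matched to (min, mean, max); a
# collapsed range returns the constant.
draw_scaled_beta <- function(n, min, mean, max, concentration = 8) {
  if (max <= min) return(rep(min, n))
  mu <- (mean - min) / (max - min)
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  min + (max - min) * rbeta(n, mu * concentration, (1 - mu) * concentration)
}

#' Generate static county covariates
#'
#' Draws one row per county: region (with configured proportions),
#' state code, population, and demographic/health/spatial covariates
#' from scaled-beta distributions matched to the configured
#' min/mean/max ranges (drawn on the log scale where the model uses
#' the log).
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per county.
#' @export
generate_counties <- function(config) {
  with_seed(child_seed(config$seed, 1), {
    n <- config$n_counties
    probs <- config$region_probs[region_levels()]
    region <- sample(region_levels(), n, replace = TRUE, prob = probs)
    pool <- region_state_pool()
    state_code <- vapply(region, function(r) sample(pool[[r]], 1), "")
    pp <- config$population_process
    population <- round(pmin(pmax(rlnorm(n, pp$meanlog, pp$sdlog), pp$min),
                             pp$max))
    out <- tibble(
      county_id = sprintf("C%05d", seq_len(n)),
      state_code = unname(state_code),
      region = region,
      population = population
    )
    for (i in seq_len(nrow(config$covariate_ranges))) {
      row <- config$covariate_ranges[i, ]
      x <- draw_scaled_beta(n, row$min, row$mean, row$max)
      out[[row$variable]] <- if (row$log) exp(x) else x
    }
    out$top10_tourist <- rbinom(n, 1, 0.252)
    out
  })
}

gauss_bump <- function(t, peak, width) exp(-0.5 * ((t - peak) / width)^2)

#' Generate weekly dynamics and capacities
#'
#' Simulates, per county, the weekly case counts (two-wave shape with
#' county severity and AR(1) multiplicative noise, capped at the
#' configured maximum rate per 100 people), the daily-average mobility
#' exposure (log scale within the configured envelope, with a
#' late-December spike), and static bed/ICU capacities. `burn_in`
#' pre-sample weeks (week_index <= 0) are included so every lagged
#' feature is available from observed week 1.
#'
#' @param counties Output of [generate_counties()].
#' @param config A [generator_config()].
#' @return Tibble with one row per county and week (including burn-in
#'   weeks), plus capacity columns.
#' @export
generate_dynamics <- function(counties, config) {
  with_seed(child_seed(config$seed, 2), {
    n <- nrow(counties)
    weeks <- seq(1L - config$burn_in, config$n_weeks)
    Tn <- length(weeks)
    cp <- config$case_process
    mp <- config$mobility_process
    kp <- config$capacity_process

    shape <- cp$baseline +
      cp$wave1_amp * gauss_bump(weeks, cp$wave1_peak, cp$wave1_width) +
      cp$wave2_amp * gauss_bump(weeks, cp$wave2_peak, cp$wave2_width)
    sev <- rlnorm(n, 0, cp$county_sdlog)

    eta <- matrix(0, nrow = Tn, ncol = n)
    if (cp$noise_sd > 0) {
      innov <- matrix(rnorm(Tn * n, 0, cp$noise_sd), nrow = Tn)
      eta[1, ] <- innov[1, ]
      if (Tn > 1) {
        for (t in 2:Tn) {
          eta[t, ] <- cp$noise_ar * eta[t - 1, ] +
            sqrt(1 - cp$noise_ar^2) * innov[t, ]
        }
      }
    }
    rate <- sweep(exp(eta), 2, sev, "*") * shape
    rate <- pmin(rate, cp$max_rate)

    ln_mob_mean <- draw_scaled_beta(n, mp$ln_min + 0.2, mp$ln_mean,
                                    mp$ln_max - 0.2)
    spike_start <- config$n_weeks - mp$spike_week_offset
    spike <- mp$spike_gain * pmin(1, pmax(0, (weeks - spike_start) / 2))
    ln_mob <- outer(spike, ln_mob_mean, "+") +
      matrix(rnorm(Tn * n, 0, mp$noise_sd), nrow = Tn)
    ln_mob <- pmin(pmax(ln_mob, mp$ln_min), mp$ln_max)

    beds_per_100k <- pmax(rlnorm(n, kp$beds_meanlog, kp$beds_sdlog), 1)
    icu_per_100k <- pmax(rlnorm(n, kp$icu_meanlog, kp$icu_sdlog), 1)
    bed_capacity <- pmax(round(beds_per_100k * counties$population / 1e5),
                         kp$beds_floor)
    icu_capacity <- pmax(round(icu_per_100k * counties$population / 1e5),
                         kp$icu_floor)

    tibble(
      county_id = rep(counties$county_id, each = Tn),
      week_index = rep(weeks, times = n),
      week_end_date = config$start_date + 7 * (rep(weeks, times = n) - 1),
      weekly_cases = as.integer(round(
        as.vector(rate) * rep(counties$population, each = Tn) / 100
      )),
      mobility_exposure = exp(as.vector(ln_mob)),
      bed_capacity = rep(bed_capacity, each = Tn),
      icu_capacity = rep(icu_capacity, each = Tn)
    )
  })
}

#' Simulate outcomes from the panel model at known truth
#'
#' Draws, per county, an error vector from a multivariate normal with
#' the ARMA-structured covariance (via its Cholesky factor) and
#' returns `y = X beta + eps` on the log-rate scale.
#'
#' @param X Design matrix whose columns match `names(truth_beta)`.
#' @param county County id per row (equal consecutive blocks, rows in
#'   week order).
#' @param truth_beta Named coefficient vector.
#' @param truth_cov A [cov_params()] triplet.
#' @param seed Integer seed (optional).
#' @return List with `y`, the mean `mu = X beta`, and `eps`.
#' @export
simulate_outcomes <- function(X, county, truth_beta, truth_cov, seed = NULL) {
  if (!setequal(colnames(X), names(truth_beta))) {
    stop_hospanel("design columns do not match truth_beta names",
                  class = "hospanel_config_error")
  }
  beta <- truth_beta[colnames(X)]
  bo <- block_order(county)
  if (!identical(bo$ord, seq_along(county))) {
    stop_hospanel("rows must be ordered county-major for simulation",
                  class = "hospanel_config_error")
  }
  Tn <- bo$n_weeks
  Z <- bo$n_counties
  fac <- omega_factor(truth_cov, Tn)
  eps <- with_seed(seed, {
    as.vector(fac$L %*% matrix(rnorm(Tn * Z), nrow = Tn))
  })
  mu <- drop(X %*% beta)
  list(y = mu + eps, mu = mu, eps = eps)
}

#' Generate a complete synthetic county-week panel
#'
#' End-to-end: static covariates, weekly dynamics, the preset design
#' for each outcome, model-based outcome draws at the configured ground
#' truth, and back-transformation to integer bed/ICU counts (floored at
#' zero and clipped to capacity, COVID demand first; clip events are
#' recorded in the `clip_log` attribute). The result passes
#' [as_county_panel()] validation and carries the generating truth in
#' its `truth` attribute.
#'
#' @param config A [generator_config()].
#' @return A validated `county_panel` tibble of
#'   `n_counties * n_weeks` records.
#' @export
generate_panel <- function(config = generator_config()) {
  counties <- generate_counties(config)
  dyn <- generate_dynamics(counties, config)
  frame <- dyn |>
    left_join(counties, by = "county_id") |>
    mutate(covid_beds = 0, noncovid_beds = 0, covid_icu = 0, noncovid_icu = 0)
  feats <- add_panel_features(frame)

  outcomes <- outcome_names()
  ylist <- list()
  mulist <- list()
  clip_log <- list()
  obs <- NULL
  for (i in seq_along(outcomes)) {
    o <- outcomes[i]
    spec <- spec_for_outcome(o)
    d <- build_design(feats, spec)
    keep <- d$index$week_index >= 1L
    X <- d$X[keep, , drop = FALSE]
    county <- d$index$county_id[keep]
    sim <- simulate_outcomes(X, county, config$truth_beta[[o]],
                             config$truth_cov[[o]],
                             seed = child_seed(config$seed, 10 + i))
    ylist[[o]] <- sim$y
    mulist[[o]] <- sim$mu
    if (is.null(obs)) {
      obs <- tibble(county_id = county,
                    week_index = d$index$week_index[keep])
    }
  }

  obs <- obs |>
    left_join(counties |> select("county_id", "population"), by = "county_id")

  # Finalize capacities: at least the configured base draw, raised to a
  # generous headroom over the county's expected peak demand (upper
  # demand quantile at `headroom_quantile` error SDs) so that capacity
  # clipping stays a rare, logged event -- the estimation model carries
  # no censoring component.
  kp <- config$capacity_process
  demand_q <- function(mu, sigma2) {
    inv_log_rate(mu + kp$headroom_quantile * sqrt(sigma2)) *
      obs$population / 1e5
  }
  peak_by_county <- function(q) {
    tapply(q, obs$county_id, max)[unique(obs$county_id)]
  }
  beds_q <- demand_q(mulist$ln_covid_hosp,
                     config$truth_cov$ln_covid_hosp$sigma2) +
    demand_q(mulist$ln_noncovid_hosp, config$truth_cov$ln_noncovid_hosp$sigma2)
  icu_q <- demand_q(mulist$ln_covid_icu,
                    config$truth_cov$ln_covid_icu$sigma2) +
    demand_q(mulist$ln_noncovid_icu, config$truth_cov$ln_noncovid_icu$sigma2)
  jitter <- with_seed(child_seed(config$seed, 20), {
    rlnorm(length(unique(obs$county_id)), kp$headroom_meanlog,
           kp$headroom_sdlog)
  })
  to_count <- function(y, pop) {
    n_floor <- sum(y < 0)
    cnt <- pmax(0, round(inv_log_rate(y) * pop / 1e5))
    list(count = cnt, n_floor = n_floor)
  }
  ch <- to_count(ylist$ln_covid_hosp, obs$population)
  nh <- to_count(ylist$ln_noncovid_hosp, obs$population)
  ci <- to_count(ylist$ln_covid_icu, obs$population)
  ni <- to_count(ylist$ln_noncovid_icu, obs$population)

  panel <- frame |>
    filter(.data$week_index >= 1L) |>
    arrange(.data$county_id, .data$week_index)
  stopifnot(identical(panel$county_id, obs$county_id),
            identical(panel$week_index, obs$week_index))

  county_ids <- unique(obs$county_id)
  bed_boost <- ceiling(jitter * peak_by_county(beds_q))
  icu_boost <- ceiling(jitter * peak_by_county(icu_q))
  panel$bed_capacity <- pmax(panel$bed_capacity,
                             bed_boost[match(panel$county_id, county_ids)])
  panel$icu_capacity <- pmax(panel$icu_capacity,
                             icu_boost[match(panel$county_id, county_ids)])

  covid_beds <- pmin(ch$count, panel$bed_capacity)
  noncovid_beds <- pmin(nh$count, panel$bed_capacity - covid_beds)
  covid_icu <- pmin(ci$count, panel$icu_capacity)
  noncovid_icu <- pmin(ni$count, panel$icu_capacity - covid_icu)
  clip_log <- list(
    floor = c(covid_beds = ch$n_floor, noncovid_beds = nh$n_floor,
              covid_icu = ci$n_floor, noncovid_icu = ni$n_floor),
    capacity = c(covid_beds = sum(covid_beds < ch$count),
                 noncovid_beds = sum(noncovid_beds < nh$count),
                 covid_icu = sum(covid_icu < ci$count),
                 noncovid_icu = sum(noncovid_icu < ni$count))
  )

  panel$covid_beds <- covid_beds
  panel$noncovid_beds <- noncovid_beds
  panel$covid_icu <- covid_icu
  panel$noncovid_icu <- noncovid_icu

  panel <- panel |> select(all_of(panel_columns()))
  panel <- as_county_panel(panel)
  attr(panel, "truth") <- list(beta = config$truth_beta,
                               cov = config$truth_cov)
  attr(panel, "clip_log") <- clip_log
  attr(panel, "config") <- config
  panel
}

#' Read / write a generator config as YAML
#'
#' Scalar process parameters, dimensions and the seed are serialized;
#' truth vectors are serialized by name. Covariance triplets are
#' stored as (sigma2, phi, rho) lists.
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `read_generator_config` returns a `generator_config`;
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  doc <- unclass(config)
  doc$start_date <- as.character(doc$start_date)
  doc$region_probs <- as.list(doc$region_probs)
  doc$truth_cov <- lapply(doc$truth_cov, unclass)
  doc$truth_beta <- lapply(doc$truth_beta, as.list)
  doc$covariate_ranges <- as.list(doc$covariate_ranges)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  doc <- yaml::read_yaml(path)
  generator_config(
    n_counties = doc$n_counties, n_weeks = doc$n_weeks, seed = doc$seed,
    truth_beta = lapply(doc$truth_beta, unlist),
    truth_cov = lapply(doc$truth_cov,
                       function(p) cov_params(p$sigma2, p$phi, p$rho)),
    covariate_ranges = as_tibble(doc$covariate_ranges),
    region_probs = unlist(doc$region_probs),
    case_process = doc$case_process,
    mobility_process = doc$mobility_process,
    capacity_process = doc$capacity_process,
    population_process = doc$population_process,
    start_date = as.Date(doc$start_date),
    burn_in = doc$burn_in
  )
}
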