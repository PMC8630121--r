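#' Outcome names
#'
#' The four log per-100k dependent variables.
#'
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function() {
  c("ln_covid_hosp", "ln_noncovid_hosp", "ln_covid_icu", "ln_noncovid_icu")
}

# Feature columns that may appear in model terms, with the number of
# prior weeks each needs before it becomes available.
feature_history <- function() {
  c(case_lag1 = 1, case_lag2 = 2, case_lag3 = 3,
    wma_3 = 3, wma_pct_diff = 3, wma_above = 3,
    ln_mob_lag2 = 2, ln_mob_lag3 = 3)
}

#' Build a model specification
#'
#' A model spec names the outcome and an ordered list of terms. A term
#' is a feature column produced by [add_panel_features()] (a base
#' covariate, a lag transform, a moving-average feature, a temporal
#' indicator or a region dummy), or an interaction written `"a:b"`
#' (elementwise product of two such columns). The intercept is always
#' present and first.
#'
#' @param outcome One of [outcome_names()].
#' @param terms Character vector of term descriptors; names must be
#'   unique.
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, terms) {
  outcome <- match.arg(outcome, outcome_names())
  terms <- as.character(terms)
  terms <- terms[terms != "(Intercept)"]
  if (anyDuplicated(terms)) {
    stop_hospanel("duplicate model terms", class = "hospanel_spec_error")
  }
  structure(
    list(outcome = outcome, terms = terms),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> outcome:", x$outcome, "\n")
  cat("  terms:", paste(c("(Intercept)", x$terms), collapse = ", "), "\n")
  invisible(x)
}

spec_term_columns <- function(spec) {
  unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
}

#' Longest history (in weeks) a spec's terms require
#'
#' @param spec A `model_spec`.
#' @return Integer number of initial weeks per county that must be
#'   dropped from fitting.
#' @export
spec_max_lag <- function(spec) {
  hist <- feature_history()
  cols <- spec_term_columns(spec)
  used <- hist[names(hist) %in% cols]
  if (length(used) == 0) 0L else as.integer(max(used))
}

#' Preset: COVID hospitalization rate model
#'
#' The full covariate layout for the COVID hospitalization outcome:
#' 2-week-lag case rate with West/South interactions, moving-average
#' difference and indicator (with regional interactions), lagged
#' mobility, demographics, health indicators, spatial factors with
#' second-wave interactions, and the two temporal indicators.
#'
#' @return A `model_spec`.
#' @export
spec_covid_hosp <- function() {
  model_spec("ln_covid_hosp", c(
    "case_lag2", "case_lag2:region_west", "case_lag2:region_south",
    "wma_pct_diff", "wma_pct_diff:region_midwest", "wma_pct_diff:region_south",
    "wma_above",
    "ln_mob_lag2", "ln_mob_lag3",
    "young_pct", "hispanic_pct", "african_american_pct", "female_pct",
    "ln_median_income",
    "ln_cardio", "hepc_per_100k",
    "region_midwest", "region_northeast", "region_northeast:since_wave2",
    "top10_tourist", "top10_tourist:since_wave2",
    "airports_per_100k",
    "since_wave2", "since_dec25"
  ))
}

#' Preset: non-COVID hospitalization rate model
#'
#' @return A `model_spec`.
#' @export
spec_noncovid_hosp <- function() {
  model_spec("ln_noncovid_hosp", c(
    "case_lag1", "case_lag2",
    "young_pct", "hispanic_pct", "african_american_pct", "female_pct",
    "ln_hiv", "ln_cancer",
    "since_dec25"
  ))
}

#' Preset specs for the ICU outcomes
#'
#' Same term layout as the corresponding hospitalization models.
#'
#' @return A `model_spec`.
#' @export
spec_covid_icu <- function() {
  s <- spec_covid_hosp()
  model_spec("ln_covid_icu", s$terms)
}

#' @rdname spec_covid_icu
#' @export
spec_noncovid_icu <- function() {
  s <- spec_noncovid_hosp()
  model_spec("ln_noncovid_icu", s$terms)
}

#' Read / write a model spec as JSON
#'
#' @param spec A `model_spec`.
#' @param path File path.
#' @return `read_model_spec` returns a `model_spec`; `write_model_spec`
#'   returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(
    list(outcome = spec$outcome, terms = spec$terms),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(x$outcome, x$terms)
}

#' Build the outcome vector and design matrix for a spec
#'
#' Restricts the panel to the weeks where every lagged term is
#' available (the first `spec_max_lag(spec)` weeks per county are
#' dropped, keeping the panel balanced), and assembles the design
#' matrix with the intercept first and columns in spec order.
#' Interaction columns are elementwise products of their factors.
#'
#' @param panel A `county_panel` (features are derived internally; a
#'   frame already carrying feature columns is used as-is).
#' @param spec A `model_spec`.
#' @return List with `y` (outcome vector), `X` (design matrix),
#'   `index` (tibble of `county_id`, `week_index` per row), `T_eff`
#'   (weeks per county) and `counties`.
#' @export
build_design <- function(panel, spec) {
  feats <- if (all(c(spec_term_columns(spec), spec$outcome) %in% names(panel))) {
    arrange(as_tibble(panel), .data$county_id, .data$week_index)
  } else {
    add_panel_features(panel)
  }
  cols <- spec_term_columns(spec)
  unknown <- setdiff(cols, names(feats))
  if (length(unknown) > 0) {
    stop_hospanel(
      paste0("spec references unknown covariate(s): ",
             paste(unknown, collapse = ", ")),
      class = "hospanel_spec_error"
    )
  }
  max_lag <- spec_max_lag(spec)
  keep <- feats$week_index > min(feats$week_index) + max_lag - 1L
  feats <- feats[keep, , drop = FALSE]

  n <- nrow(feats)
  X <- matrix(0, nrow = n, ncol = 1 + length(spec$terms))
  colnames(X) <- c("(Intercept)", spec$terms)
  X[, 1] <- 1
  for (term in spec$terms) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- rep(1, n)
    for (p in parts) col <- col * feats[[p]]
    X[, term] <- col
  }
  if (anyNA(X)) {
    stop_hospanel("design matrix contains missing values after lag trimming",
                  class = "hospanel_spec_error")
  }
  per_county <- table(feats$county_id)
  if (length(unique(as.integer(per_county))) != 1) {
    stop_hospanel("design rows are unbalanced across counties",
                  class = "hospanel_balance_error")
  }
  list(
    y = feats[[spec$outcome]],
    X = X,
    index = tibble(county_id = feats$county_id,
                   week_index = feats$week_index,
                   week_end_date = feats$week_end_date),
    T_eff = as.integer(per_county[1]),
    counties = names(per_county)
  )
}
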