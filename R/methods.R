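#' @export
print.arma_lmm <- function(x, ...) {
  cat("Panel linear mixed model (REML, ARMA residual covariance)\n")
  cat(sprintf("  outcome: %s | counties: %d | weeks: %d | obs: %d\n",
              x$spec$outcome, x$n_counties, x$n_weeks, x$nobs))
  cat(sprintf("  sigma2 = %.4f, phi = %.4f, rho = %.4f\n",
              x$cov_params$sigma2, x$cov_params$phi, x$cov_params$rho))
  cat(sprintf("  REML log-likelihood = %.2f | converged: %s\n",
              x$reml_loglik, x$converged))
  cat("\nCoefficients:\n")
  print(round(tidy(x)[, c("term", "estimate", "std.error", "statistic")],
              4), n = Inf)
  invisible(x)
}

#' Tidy the coefficient table of a fitted panel model
#'
#' @param x An `arma_lmm` fit.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`
#'   and a large-sample normal `p.value`.
#' @method tidy arma_lmm
#' @export
tidy.arma_lmm <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$t_stats),
    p.value = 2 * stats::pnorm(-abs(unname(x$t_stats)))
  )
}

#' One-row model summary
#'
#' @param x An `arma_lmm` fit.
#' @param ... Unused.
#' @return Tibble with the covariance parameters, REML log-likelihood
#'   and dimensions.
#' @method glance arma_lmm
#' @export
glance.arma_lmm <- function(x, ...) {
  tibble(
    sigma2 = x$cov_params$sigma2,
    phi = x$cov_params$phi,
    rho = x$cov_params$rho,
    reml_loglik = x$reml_loglik,
    nobs = x$nobs,
    n_counties = x$n_counties,
    n_weeks = x$n_weeks,
    converged = x$converged
  )
}

#' Coefficient plot for a fitted panel model
#'
#' Dot-and-whisker plot of the estimates with approximate 95%
#' intervals (excluding the intercept by default).
#'
#' @param object An `arma_lmm` fit.
#' @param intercept Include the intercept row?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arma_lmm
#' @export
autoplot.arma_lmm <- function(object, intercept = FALSE, ...) {
  td <- tidy(object)
  if (!intercept) td <- filter(td, .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL)
}

#' Serialize / restore a fitted model as JSON
#'
#' The document carries the spec, the coefficient table (name,
#' estimate, SE, t-statistic), the covariance parameters and the REML
#' log-likelihood.
#'
#' @param fit An `arma_lmm` fit.
#' @param path File path.
#' @return `read_model` returns an `arma_lmm` (without the optimizer
#'   trace or `beta_cov`); `write_model` returns `path` invisibly.
#' @export
write_model <- function(fit, path) {
  doc <- list(
    spec = list(outcome = fit$spec$outcome, terms = fit$spec$terms),
    coefficients = tidy(fit),
    cov_params = unclass(fit$cov_params),
    reml_loglik = fit$reml_loglik,
    n_counties = fit$n_counties,
    n_weeks = fit$n_weeks,
    nobs = fit$nobs,
    converged = fit$converged
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- setNames(doc$coefficients$estimate, doc$coefficients$term)
  se <- setNames(doc$coefficients$std.error, doc$coefficients$term)
  structure(
    list(
      spec = model_spec(doc$spec$outcome, doc$spec$terms),
      beta = beta,
      beta_cov = NULL,
      se = se,
      t_stats = beta / se,
      cov_params = cov_params(doc$cov_params$sigma2, doc$cov_params$phi,
                              doc$cov_params$rho),
      reml_loglik = doc$reml_loglik,
      n_counties = doc$n_counties,
      n_weeks = doc$n_weeks,
      nobs = doc$nobs,
      converged = doc$converged,
      trace = NULL
    ),
    class = "arma_lmm"
  )
}
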