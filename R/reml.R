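# Generalized least squares and REML for the balanced county-week
# panel. All counties share one T_eff x T_eff covariance Omega, so each
# likelihood evaluation factorizes Omega once (O(T^3)) and whitens the
# stacked design by reshaping to T_eff x (Z * p) (O(Z * T^2 * p)).

# Order rows county-major and validate that every county contributes
# the same number of consecutive rows (week order preserved).
block_order <- function(county) {
  n <- length(county)
  tab <- table(county)
  if (length(unique(as.integer(tab))) != 1) {
    stop_hospanel("counties contribute unequal numbers of rows",
                  class = "hospanel_balance_error")
  }
  list(ord = order(as.character(county), method = "radix"),
       n_weeks = as.integer(tab[1]),
       n_counties = length(tab))
}

# Whiten y and X by the shared factor L (forward solve per county
# block), returning whitened copies plus bookkeeping.
whiten <- function(y, X, county, L) {
  bo <- block_order(county)
  Tn <- bo$n_weeks
  n <- length(y)
  p <- ncol(X)
  yw <- as.vector(forwardsolve(L, matrix(y[bo$ord], nrow = Tn)))
  Xw <- matrix(
    as.vector(forwardsolve(L, matrix(X[bo$ord, , drop = FALSE], nrow = Tn))),
    nrow = n, ncol = p
  )
  colnames(Xw) <- colnames(X)
  list(yw = yw, Xw = Xw, n_weeks = Tn, n_counties = bo$n_counties)
}

gls_pieces <- function(y, X, county, params) {
  bo <- block_order(county)
  fac <- omega_factor(params, bo$n_weeks)
  w <- whiten(y, X, county, fac$L)
  XtX <- crossprod(w$Xw)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) {
    qrX <- qr(w$Xw)
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop_hospanel(
      paste0("design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", ")),
      class = "hospanel_singular_error"
    )
  }
  beta <- backsolve(R, forwardsolve(t(R), crossprod(w$Xw, w$yw)))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  r <- w$yw - w$Xw %*% beta
  list(
    beta = beta,
    beta_cov = chol2inv(R),
    rss = sum(r^2),
    logdet_xtx = 2 * sum(log(diag(R))),
    logdet_omega = fac$logdet,
    n = length(y), p = ncol(X),
    n_weeks = w$n_weeks, n_counties = w$n_counties
  )
}

#' Generalized least squares coefficients given covariance parameters
#'
#' Computes `beta = (sum_z X_z' Omega^-1 X_z)^-1 (sum_z X_z' Omega^-1 y_z)`
#' and its covariance over the balanced per-county blocks.
#'
#' @param y Stacked outcome vector (rows in week order within county).
#' @param X Stacked design matrix conformable with `y`.
#' @param county County identifier per row; every county must
#'   contribute the same number of rows.
#' @param params A [cov_params()] triplet.
#' @return List with named `beta` and `beta_cov`.
#' @export
gls_beta <- function(y, X, county, params) {
  g <- gls_pieces(y, X, county, params)
  dimnames(g$beta_cov) <- list(names(g$beta), names(g$beta))
  list(beta = g$beta, beta_cov = g$beta_cov)
}

#' Restricted (REML) log-likelihood at given covariance parameters
#'
#' Evaluates
#' `-1/2 * [(N - p) log 2 pi + Z log|Omega| + log|sum_z X_z' Omega^-1 X_z|
#'  + sum_z r_z' Omega^-1 r_z]`
#' with `r_z` the GLS residuals at `params`.
#'
#' @inheritParams gls_beta
#' @return The REML log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, county, params) {
  g <- gls_pieces(y, X, county, params)
  -0.5 * ((g$n - g$p) * log(2 * pi) +
            g$n_counties * g$logdet_omega +
            g$logdet_xtx +
            g$rss)
}

#' Optimizer settings for [fit_reml()]
#'
#' @param starts List of numeric `c(phi, rho)` starting points for the
#'   deterministic multistart search over the correlation parameters
#'   (the error variance is profiled out in closed form).
#' @param fix Optional named list fixing any of `sigma2`, `phi`, `rho`
#'   at given values (e.g. `list(phi = 0, rho = 0)` for independent
#'   errors).
#' @param reltol Relative convergence tolerance on the profiled
#'   log-likelihood.
#' @param maxit Maximum iterations per start.
#' @return A list of settings.
#' @export
reml_control <- function(starts = list(c(0.3, 0.5), c(0.7, 0.9), c(0.9, 0.97)),
                         fix = NULL,
                         reltol = 1e-10,
                         maxit = 500) {
  list(starts = starts, fix = fix, reltol = reltol, maxit = maxit)
}

# Profiled negative REML log-likelihood over free correlation
# parameters (unconstrained atanh scale). sigma2 is profiled unless
# fixed.
profiled_negll <- function(u, free, fix, y, X, county) {
  vals <- fix
  vals[free] <- tanh(u)
  phi <- vals[["phi"]]
  rho <- vals[["rho"]]
  sigma2 <- vals[["sigma2"]]
  g <- tryCatch(
    gls_pieces(y, X, county, cov_params(1, phi, rho)),
    error = function(e) NULL
  )
  if (is.null(g)) return(1e10)
  if (is.null(sigma2)) sigma2 <- g$rss / (g$n - g$p)
  if (!is.finite(sigma2) || sigma2 <= 0) return(1e10)
  ll <- -0.5 * ((g$n - g$p) * (log(2 * pi) + log(sigma2)) +
                  g$n_counties * g$logdet_omega +
                  g$logdet_xtx +
                  g$rss / sigma2)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the panel linear mixed model by REML
#'
#' Estimates the coefficient vector and the ARMA-structured residual
#' covariance (`sigma2`, `phi`, `rho`) of a balanced county-week panel
#' model by restricted maximum likelihood: the error variance is
#' profiled out in closed form and the two correlation parameters are
#' maximized on an unconstrained `atanh` scale by a deterministic
#' multistart Nelder-Mead search with a quasi-Newton polish.
#' Coefficients are exact generalized least squares at the optimum.
#'
#' @param panel A `county_panel`.
#' @param spec A [model_spec()].
#' @param control A [reml_control()] list.
#' @return An object of class `arma_lmm` with elements `beta`,
#'   `beta_cov`, `t_stats`, `cov_params`, `reml_loglik`, `n_counties`,
#'   `n_weeks`, `nobs`, `converged` and an optimizer `trace`. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_reml <- function(panel, spec, control = reml_control()) {
  d <- build_design(panel, spec)
  fit_reml_design(d, spec, control)
}

# Fit from a prebuilt design (exposed for simulation workflows).
#' @rdname fit_reml
#' @param design A design list from [build_design()] (alternative entry
#'   point used when the design has been built already).
#' @export
fit_reml_design <- function(design, spec, control = reml_control()) {
  y <- design$y
  X <- design$X
  county <- design$index$county_id
  if (design$T_eff < 2 || length(design$counties) < 2) {
    stop_hospanel("need at least 2 counties and 2 weeks to fit",
                  class = "hospanel_parameter_error")
  }

  fix <- control$fix %||% list()
  free <- setdiff(c("phi", "rho"), names(fix))
  trace <- list()
  best <- NULL

  if (length(free) == 0) {
    val <- profiled_negll(numeric(0), character(0), fix, y, X, county)
    best <- list(par = numeric(0), value = val, convergence = 0L,
                 start = numeric(0))
    trace <- list(best)
  } else {
    for (st in control$starts) {
      names(st) <- c("phi", "rho")[seq_along(st)]
      u0 <- atanh(pmin(pmax(st[free], -0.995), 0.995))
      opt <- stats::optim(
        u0, profiled_negll, free = free, fix = fix,
        y = y, X = X, county = county,
        method = "Nelder-Mead",
        control = list(reltol = control$reltol, maxit = control$maxit)
      )
      polish <- tryCatch(
        stats::optim(
          opt$par, profiled_negll, free = free, fix = fix,
          y = y, X = X, county = county,
          method = "BFGS",
          control = list(reltol = control$reltol, maxit = 100)
        ),
        error = function(e) opt
      )
      if (polish$value <= opt$value) opt <- polish
      rec <- list(start = st, par = tanh(opt$par), value = opt$value,
                  convergence = opt$convergence, counts = opt$counts)
      trace <- c(trace, list(rec))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }

  vals <- fix
  if (length(free) > 0) vals[free] <- tanh(best$par)
  phi <- vals[["phi"]]
  rho <- vals[["rho"]]
  g1 <- gls_pieces(y, X, county, cov_params(1, phi, rho))
  sigma2 <- vals[["sigma2"]] %||% (g1$rss / (g1$n - g1$p))
  params <- cov_params(sigma2, phi, rho)

  gb <- gls_beta(y, X, county, params)
  ll <- reml_loglik(y, X, county, params)
  se <- sqrt(diag(gb$beta_cov))
  t_stats <- gb$beta / se

  structure(
    list(
      spec = spec,
      beta = gb$beta,
      beta_cov = gb$beta_cov,
      se = se,
      t_stats = t_stats,
      cov_params = params,
      reml_loglik = ll,
      n_counties = g1$n_counties,
      n_weeks = g1$n_weeks,
      nobs = g1$n,
      converged = best$convergence == 0 && best$value < 1e10,
      trace = trace
    ),
    class = "arma_lmm"
  )
}
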