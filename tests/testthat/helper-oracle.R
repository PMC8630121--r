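# Independent brute-force REML oracle: stacks the full block-diagonal
# covariance and evaluates the restricted likelihood with dense
# determinants and solves. Deliberately shares no code with the
# package's whitened per-block path.
oracle_reml_loglik <- function(y, X, county, params) {
  ids <- sort(unique(as.character(county)))
  ord <- order(as.character(county), method = "radix")
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  Tn <- length(y) / length(ids)
  Om <- build_omega(params, Tn)
  V <- kronecker(diag(length(ids)), Om)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  as.numeric(
    -0.5 * ((n - p) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r)
  )
}

# Random small fitting instance for oracle-equivalence checks.
random_instance <- function(n_counties, n_weeks, p = 3) {
  county <- rep(sprintf("Z%02d", seq_len(n_counties)), each = n_weeks)
  X <- cbind(1, matrix(rnorm(n_counties * n_weeks * (p - 1)), ncol = p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  y <- rnorm(n_counties * n_weeks)
  params <- cov_params(
    sigma2 = runif(1, 0.2, 3),
    phi = runif(1, 0, 0.9),
    rho = runif(1, -0.85, 0.85)
  )
  list(y = y, X = X, county = county, params = params)
}
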