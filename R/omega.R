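#' Within-county residual covariance parameters
#'
#' The triplet governing the ARMA-structured repeated-measures
#' covariance: the error variance `sigma2`, the common correlation
#' factor `phi` shared by all pairs of weeks, and the dampening
#' parameter `rho` that reduces the correlation as weeks grow apart.
#' The lag-`k` correlation between two weeks of the same county is
#' `phi * rho^k`.
#'
#' @param sigma2 Error variance, `> 0` (squared log-rate units).
#' @param phi Common correlation factor, in (-1, 1).
#' @param rho Dampening parameter, in (-1, 1) (boundary values allowed
#'   for degenerate constructions, but rejected by the fitter).
#' @return A `cov_params` object.
#' @export
cov_params <- function(sigma2, phi, rho) {
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop_hospanel("sigma2 must be positive", class = "hospanel_parameter_error")
  }
  if (!is.finite(phi) || !is.finite(rho) || abs(phi) > 1 || abs(rho) > 1) {
    stop_hospanel("phi and rho must lie in [-1, 1]",
                  class = "hospanel_parameter_error")
  }
  structure(list(sigma2 = sigma2, phi = phi, rho = rho),
            class = "cov_params")
}

#' @export
print.cov_params <- function(x, ...) {
  cat(sprintf("<cov_params> sigma2 = %.4g, phi = %.4g, rho = %.4g\n",
              x$sigma2, x$phi, x$rho))
  invisible(x)
}

#' Build the within-county covariance matrix
#'
#' `Omega[i, i] = sigma2` and `Omega[i, j] = sigma2 * phi * rho^|i-j|`
#' for `i != j`: the first off-diagonal is `sigma2 * phi * rho`, the
#' corner `sigma2 * phi * rho^(T-1)`.
#'
#' @param params A [cov_params()] triplet.
#' @param n_weeks Number of weeks `T >= 1`.
#' @return A symmetric `T x T` matrix.
#' @export
build_omega <- function(params, n_weeks) {
  if (!is.numeric(n_weeks) || length(n_weeks) != 1 || n_weeks < 1) {
    stop_hospanel("n_weeks must be a positive integer",
                  class = "hospanel_parameter_error")
  }
  n_weeks <- as.integer(n_weeks)
  k <- abs(outer(seq_len(n_weeks), seq_len(n_weeks), "-"))
  C <- params$phi * params$rho^k
  diag(C) <- 1
  params$sigma2 * C
}

#' Cholesky factor and log-determinant of the covariance
#'
#' @param params A [cov_params()] triplet.
#' @param n_weeks Number of weeks.
#' @return List with `L` (lower-triangular factor, `L %*% t(L) = Omega`)
#'   and `logdet` (log-determinant of Omega). Errors with a
#'   not-positive-definite message if the factorization fails.
#' @export
omega_factor <- function(params, n_weeks) {
  Om <- build_omega(params, n_weeks)
  U <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(U)) {
    stop_hospanel(
      sprintf("covariance not positive definite at sigma2=%.4g, phi=%.4g, rho=%.4g",
              params$sigma2, params$phi, params$rho),
      class = "hospanel_pd_error"
    )
  }
  list(L = t(U), logdet = 2 * sum(log(diag(U))))
}
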