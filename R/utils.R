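stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# log density of N(mean, V) at x, via Cholesky; V must be PD
mvn_logdens <- function(x, mean, V) {
  k <- length(mean)
  L <- chol(V)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# multivariate t with df nu, location mu, scale matrix S
mvt_logdens <- function(x, mu, S, nu) {
  k <- length(mu)
  L <- chol(S)
  z <- backsolve(L, x - mu, transpose = TRUE)
  lgamma((nu + k) / 2) - lgamma(nu / 2) - 0.5 * k * log(nu * pi) -
    sum(log(diag(L))) - 0.5 * (nu + k) * log1p(sum(z^2) / nu)
}

# n draws from multivariate t(mu, S, nu); rows are draws
mvt_draw <- function(n, mu, S, nu) {
  k <- length(mu)
  L <- chol(S)
  Z <- matrix(rnorm(n * k), n, k) %*% L
  w <- sqrt(nu / rchisq(n, df = nu))
  sweep(Z * w, 2, mu, `+`)
}

#' Test a matrix for symmetric positive definiteness
#'
#' Symmetry is required to machine tolerance; positive definiteness is
#' declared when the smallest eigenvalue exceeds `tol` (default 1e-10),
#' a numerically robust criterion for the small covariance matrices used
#' throughout the package.
#'
#' @param V square numeric matrix
#' @param tol smallest admissible eigenvalue
#' @return `TRUE` or `FALSE`
#' @export
is_positive_definite <- function(V, tol = 1e-10) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) return(FALSE)
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V)))) return(FALSE)
  min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) > tol
}
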