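#' @useDynLib masemsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor nlminb pchisq qnorm rnorm sd var
NULL

# Variable order used throughout: (Y1, Y2, X1, X2).  Y1 is the mediator,
# Y2 the outcome, X1 and X2 the exogenous variables.
.var_names <- c("Y1", "Y2", "X1", "X2")

# Off-diagonal order of the 6 unique correlations of a 4x4 matrix:
# (2,1), (3,1), (4,1), (3,2), (4,2), (4,3).
.vec_idx <- cbind(i = c(2L, 3L, 4L, 3L, 4L, 4L),
                  j = c(1L, 1L, 1L, 2L, 2L, 3L))
.vec_names <- c("r21", "r31", "r41", "r32", "r42", "r43")

#' Structural parameters of the four-variable recursive path model
#'
#' Bundles the coefficient matrices of the model
#' \eqn{Y = \Gamma X + B Y + \zeta}: two exogenous variables X1, X2 with
#' covariance `phi`, a mediator Y1 and an outcome Y2 with disturbance
#' covariance `psi` (diagonal).  `beta` must be strictly lower triangular
#' (recursive model), and only its (2,1) element may be nonzero.
#'
#' @param gamma 2x2 matrix of regressions of Y on X; element (2,2) is
#'   structurally zero (no direct X2 -> Y2 path, the model's single
#'   overidentifying restriction).
#' @param beta 2x2 strictly lower triangular matrix of regressions among
#'   Y (only the Y1 -> Y2 path `beta[2, 1]`).
#' @param phi 2x2 symmetric positive definite covariance of X.
#' @param psi 2x2 diagonal nonnegative disturbance covariance.
#' @return An object of class `path_params`.
#' @examples
#' p <- path_params(gamma = rbind(c(0.4, 0.5), c(0.3, 0)),
#'                  beta = rbind(c(0, 0), c(0.5, 0)),
#'                  phi = rbind(c(1, 0.2), c(0.2, 1)),
#'                  psi = diag(c(0.51, 0.51)))
#' implied_covariance(p)
#' @export
path_params <- function(gamma, beta, phi, psi) {
  gamma <- as.matrix(gamma); beta <- as.matrix(beta)
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(all(dim(gamma) == 2L), all(dim(beta) == 2L),
            all(dim(phi) == 2L), all(dim(psi) == 2L))
  if (any(beta[upper.tri(beta, diag = TRUE)] != 0))
    stop("'beta' must be strictly lower triangular (recursive model)")
  if (gamma[2L, 2L] != 0)
    stop("gamma[2, 2] is structurally zero in this model")
  if (max(abs(phi - t(phi))) > 1e-12)
    stop("'phi' must be symmetric")
  if (any(eigen(phi, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'phi' must be positive definite")
  if (max(abs(psi - diag(diag(psi)))) > 1e-12 || any(diag(psi) < 0))
    stop("'psi' must be diagonal with nonnegative entries")
  structure(list(gamma = gamma, beta = beta, phi = phi, psi = psi),
            class = "path_params")
}

#' @export
print.path_params <- function(x, ...) {
  cat("Recursive path model parameters (Y = Gamma X + B Y + zeta)\n")
  cat("gamma:\n"); print(x$gamma)
  cat("beta:\n"); print(x$beta)
  cat("phi:\n"); print(x$phi)
  cat("psi:\n"); print(x$psi)
  invisible(x)
}

#' Default population parameter values of the simulation model
#'
#' The parameter set whose implied covariance matrix is the population
#' correlation matrix [sigma_pop()]: all four implied variances equal 1,
#' so the implied covariance matrix doubles as a correlation matrix.
#'
#' @return A `path_params` object with gamma11 = 0.4, gamma12 = 0.5,
#'   gamma21 = 0.3, beta21 = 0.5, phi12 = 0.2 (unit X variances) and
#'   psi11 = psi22 = 0.51.
#' @export
default_path_params <- function() {
  path_params(gamma = rbind(c(0.4, 0.5), c(0.3, 0)),
              beta  = rbind(c(0, 0), c(0.5, 0)),
              phi   = rbind(c(1, 0.2), c(0.2, 1)),
              psi   = diag(c(0.51, 0.51)))
}

#' Model-implied covariance matrix of the path model
#'
#' Computes the covariance matrix implied by a recursive path model in
#' variable order (Y1, Y2, X1, X2) from the block formula: the Y-block is
#' \eqn{(I-B)^{-1}(\Gamma\Phi\Gamma' + \Psi)(I-B)'^{-1}}, the cross block
#' \eqn{(I-B)^{-1}\Gamma\Phi}, and the X-block \eqn{\Phi}.
#'
#' @param params A [path_params()] object.
#' @return A 4x4 symmetric matrix with dimnames (Y1, Y2, X1, X2).
#' @export
implied_covariance <- function(params) {
  stopifnot(inherits(params, "path_params"))
  ImB <- diag(2) - params$beta
  if (abs(det(ImB)) < 1e-12)
    stop("singular (I - B): non-recursive model specification")
  A <- solve(ImB)
  GP <- params$gamma %*% params$phi
  Syy <- A %*% (GP %*% t(params$gamma) + params$psi) %*% t(A)
  Syx <- A %*% GP
  S <- rbind(cbind(Syy, Syx), cbind(t(Syx), params$phi))
  S <- (S + t(S)) / 2
  dimnames(S) <- list(.var_names, .var_names)
  S
}

#' Extract the 6 unique correlations of a 4x4 correlation matrix
#'
#' Vectorization order is (2,1), (3,1), (4,1), (3,2), (4,2), (4,3) under
#' variable order (Y1, Y2, X1, X2); it round-trips with [corr_matrix()].
#'
#' @param R 4x4 symmetric matrix with unit diagonal.
#' @return Named numeric vector of length 6.
#' @export
corr_vector <- function(R) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == 4L))
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("'R' must have unit diagonal")
  v <- R[.vec_idx]
  names(v) <- .vec_names
  v
}

#' Rebuild a 4x4 correlation matrix from its 6-vector of correlations
#'
#' Inverse of [corr_vector()].
#'
#' @param v Numeric vector of length 6 in the fixed element order.
#' @return 4x4 symmetric matrix with unit diagonal.
#' @export
corr_matrix <- function(v) {
  stopifnot(length(v) == 6L, all(abs(v) < 1))
  R <- diag(4)
  R[.vec_idx] <- v
  R[.vec_idx[, 2:1]] <- v
  dimnames(R) <- list(.var_names, .var_names)
  R
}

#' Homogeneous-population correlation matrix
#'
#' The correlation matrix implied by [default_path_params()], used as the
#' common population matrix for homogeneous studies.  Its unique
#' correlations are (0.65, 0.50, 0.58, 0.55, 0.35, 0.20).
#'
#' @return 4x4 correlation matrix.
#' @export
sigma_pop <- function() {
  corr_matrix(c(0.65, 0.50, 0.58, 0.55, 0.35, 0.20))
}

#' Alternative population correlation matrix for heterogeneous studies
#'
#' The second fixed population matrix of the mixture design; studies
#' flagged as heterogeneous are drawn from it instead of [sigma_pop()].
#' Stored as the exact constants (0.45, 0.30, 0.40, 0.35, 0.19, 0.15).
#'
#' @return 4x4 correlation matrix.
#' @export
sigma_prime <- function() {
  corr_matrix(c(0.45, 0.30, 0.40, 0.35, 0.19, 0.15))
}

#' Disturbance variances that standardize the path model
#'
#' Given the 5 free parameters (gamma11, gamma12, gamma21, beta21, phi12)
#' of the correlation-structure parameterization (phi11 = phi22 = 1),
#' returns the disturbance variances (psi11, psi22) that make all four
#' implied variances exactly 1.
#'
#' @param theta Numeric vector (gamma11, gamma12, gamma21, beta21, phi12).
#' @return Named numeric vector c(psi11, psi22); errors if either derived
#'   variance is not positive (inadmissible theta).
#' @export
derived_psi <- function(theta) {
  stopifnot(length(theta) == 5L)
  g11 <- theta[1L]; g12 <- theta[2L]; g21 <- theta[3L]
  b21 <- theta[4L]; p12 <- theta[5L]
  psi1 <- 1 - (g11^2 + 2 * g11 * g12 * p12 + g12^2)
  # var(Y2) = u' Phi u + beta21^2 psi11 + psi22, u = reduced-form X loadings
  u <- c(g11 * b21 + g21, g12 * b21)
  psi2 <- 1 - (u[1L]^2 + 2 * u[1L] * u[2L] * p12 + u[2L]^2) - b21^2 * psi1
  if (psi1 <= 0 || psi2 <= 0)
    stop("inadmissible theta: derived disturbance variance <= 0")
  c(psi11 = psi1, psi22 = psi2)
}

# Analytic Jacobian (2x5) of derived_psi, used for delta-method SEs.
derived_psi_jacobian <- function(theta) {
  g11 <- theta[1L]; g12 <- theta[2L]; g21 <- theta[3L]
  b21 <- theta[4L]; p12 <- theta[5L]
  d1 <- c(-2 * (g11 + g12 * p12), -2 * (g12 + g11 * p12), 0, 0,
          -2 * g11 * g12)
  u <- c(g11 * b21 + g21, g12 * b21)
  v <- c(u[1L] + p12 * u[2L], p12 * u[1L] + u[2L])  # Phi %*% u
  psi1 <- 1 - (g11^2 + 2 * g11 * g12 * p12 + g12^2)
  d2 <- c(-2 * v[1L] * b21 - b21^2 * d1[1L],
          -2 * v[2L] * b21 - b21^2 * d1[2L],
          -2 * v[1L],
          -2 * (v[1L] * g11 + v[2L] * g12) - 2 * b21 * psi1,
          -2 * u[1L] * u[2L] - b21^2 * d1[5L])
  rbind(psi11 = d1, psi22 = d2)
}

#' Correlation vector implied by the 5 free path parameters
#'
#' Maps theta = (gamma11, gamma12, gamma21, beta21, phi12) to the 6
#' implied correlations, with phi11 = phi22 = 1 and disturbance variances
#' set by [derived_psi()] so that all implied variances are 1.  This is
#' the correlation-structure map used by the WLS (ADF) stage-2 fit.
#'
#' @param theta Numeric vector (gamma11, gamma12, gamma21, beta21, phi12).
#' @return Named numeric vector of the 6 implied correlations.
#' @examples
#' implied_corr_vector(c(0.4, 0.5, 0.3, 0.5, 0.2))  # (0.65, 0.50, ...)
#' @export
implied_corr_vector <- function(theta) {
  psi <- derived_psi(theta)
  p <- path_params(gamma = rbind(theta[1:2], c(theta[3L], 0)),
                   beta  = rbind(c(0, 0), c(theta[4L], 0)),
                   phi   = rbind(c(1, theta[5L]), c(theta[5L], 1)),
                   psi   = diag(unname(psi)))
  corr_vector(implied_covariance(p))
}

#' Export a population correlation matrix as CSV
#'
#' Writes a 4x4 correlation matrix as plain CSV with a header row of
#' variable names, the exchange format consumed by downstream tools.
#'
#' @param R 4x4 correlation matrix (e.g. [sigma_pop()]).
#' @param file Path of the CSV file to write.
#' @return `file`, invisibly.
#' @export
write_population_csv <- function(R, file) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == 4L))
  dimnames(R) <- list(.var_names, .var_names)
  utils::write.csv(R, file, row.names = TRUE)
  invisible(file)
}
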