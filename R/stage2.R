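new_stage2_result <- function(route, estimates, ses, chisq, df, converged,
                              N = NA_real_, fmin = NA_real_) {
  p <- pchisq(chisq, df, lower.tail = FALSE)
  structure(list(route = route, estimates = estimates, ses = ses,
                 chisq = chisq, df = df, p = p, converged = converged,
                 N = N, fmin = fmin),
            class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  cat(sprintf("Stage 2 (%s): chisq(df = %d) = %.4f, p = %.4g%s\n",
              x$route, x$df, x$chisq, x$p,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates, se = x$ses)
  print(round(tab, 4))
  invisible(x)
}

# Deterministic jittered restarts: perturb a start vector with fixed
# pseudo-random offsets without disturbing the caller's RNG stream.
jittered_starts <- function(start, n_restarts, scale = 0.25) {
  seed_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(seed_state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", seed_state, envir = globalenv())
  })
  set.seed(285714L)
  lapply(seq_len(n_restarts), function(i)
    start + rnorm(length(start), sd = scale))
}

run_nlminb <- function(start, fn, gr, lower = -Inf, upper = Inf,
                       restarts = 10L) {
  opt <- nlminb(start, fn, gr, lower = lower, upper = upper,
                control = list(rel.tol = 1e-10, iter.max = 500))
  ok <- function(o) o$convergence == 0 && o$objective < 1e9
  if (!ok(opt) && restarts > 0) {
    for (s in jittered_starts(start, restarts)) {
      cand <- tryCatch(
        nlminb(s, fn, gr, lower = lower, upper = upper,
               control = list(rel.tol = 1e-10, iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (ok(cand) || cand$objective < opt$objective)) {
        opt <- cand
        if (ok(opt)) break
      }
    }
  }
  opt
}

.ml_names <- c("gamma11", "gamma12", "gamma21", "beta21",
               "phi11", "phi22", "phi12", "psi11", "psi22")
.wls_names <- c("gamma11", "gamma12", "gamma21", "beta21", "phi12",
                "psi11", "psi22")

#' Fit the path model to a pooled matrix by maximum likelihood
#'
#' The univariate-route stage-2 fit: the pooled correlation matrix is
#' treated as a sample covariance matrix from `N` observations (N the
#' total sample size of the meta-analysis) and the normal-theory ML
#' discrepancy \eqn{F = \ln|\Sigma(\theta)| - \ln|S| +
#' tr(S\Sigma(\theta)^{-1}) - 4} is minimized over the 9 free parameters
#' (gamma11, gamma12, gamma21, beta21, phi11, phi22, phi12, psi11,
#' psi22).  The model chi-square is `(N - 1) * F` at the minimum with 1
#' degree of freedom; standard errors come from the inverse Hessian of
#' `(N - 1)/2 * F` (central differences of the analytic gradient).
#'
#' Treating a correlation matrix as a covariance matrix is the
#' conventional univariate-route shortcut; its consequences for the
#' chi-square and the standard errors are part of what the simulation
#' harness measures.
#'
#' @param pooled 4x4 pooled correlation (or covariance) matrix, positive
#'   definite, variable order (Y1, Y2, X1, X2).
#' @param N Total sample size.
#' @param n_multiplier `"N-1"` (classic SEM convention, default) or
#'   `"N"`: multiplier of the discrepancy in the chi-square.
#' @param start Starting values; default 0.1 for all paths and the X
#'   covariance, 1 for variances.
#' @param restarts Jittered restarts attempted on nonconvergence.
#' @return A `stage2_result` with 9 estimates, SEs, `chisq` and df = 1.
#' @export
fit_ml <- function(pooled, N, n_multiplier = c("N-1", "N"),
                   start = NULL, restarts = 10L) {
  n_multiplier <- match.arg(n_multiplier)
  pooled <- as.matrix(pooled)
  stopifnot(all(dim(pooled) == 4L), N > 1)
  if (is.null(start)) start <- c(0.1, 0.1, 0.1, 0.1, 1, 1, 0.1, 1, 1)
  fn <- function(th) cpp_ml_objgrad(th, pooled)$value
  gr <- function(th) cpp_ml_objgrad(th, pooled)$gradient
  lower <- c(rep(-Inf, 4), 1e-6, 1e-6, -Inf, 1e-6, 1e-6)
  opt <- run_nlminb(start, fn, gr, lower = lower, restarts = restarts)
  est <- opt$par
  names(est) <- .ml_names
  mult <- if (n_multiplier == "N-1") N - 1 else N
  chisq <- max(0, mult * opt$objective)
  converged <- opt$convergence == 0 && opt$objective < 1e9 &&
    est["psi11"] > 1e-6 && est["psi22"] > 1e-6
  # observed information = (mult/2) * Hessian of F
  H <- matrix(NA_real_, 9, 9)
  h <- 1e-5
  for (q in 1:9) {
    e <- numeric(9); e[q] <- h
    H[, q] <- (gr(est + e) - gr(est - e)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ses <- rep(NA_real_, 9)
  cov <- tryCatch(solve((mult / 2) * H), error = function(e) NULL)
  if (!is.null(cov) && all(diag(cov) > 0)) {
    ses <- sqrt(diag(cov))
  } else converged <- FALSE
  names(ses) <- .ml_names
  new_stage2_result("ML", est, ses, chisq, df = 1L,
                    converged = converged, N = N, fmin = opt$objective)
}

#' Fit the path model to a pooled correlation vector by WLS (ADF)
#'
#' The multivariate-route stage-2 fit: minimizes the quadratic form
#' \eqn{F = (\bar r - \rho(\theta))' V^{-1} (\bar r - \rho(\theta))}
#' over the 5 free parameters of the standardized model
#' ([implied_corr_vector()]), where V is the stage-1 asymptotic
#' covariance of the pooled correlations (already on the 1/N scale).
#' The model chi-square is F at the minimum with 6 - 5 = 1 degree of
#' freedom.  Standard errors of the free parameters come from
#' \eqn{(J'V^{-1}J)^{-1}} with J the analytic Jacobian of
#' \eqn{\rho(\theta)}; the derived disturbance variances psi11, psi22
#' are reported with delta-method SEs.
#'
#' @param pooled Length-6 pooled correlation vector.
#' @param acov 6x6 positive definite asymptotic covariance of `pooled`.
#' @param start Starting values for (gamma11, gamma12, gamma21, beta21,
#'   phi12); default 0.1 each.
#' @param restarts Jittered restarts attempted on nonconvergence.
#' @return A `stage2_result` with 7 estimates (5 free + 2 derived),
#'   SEs, `chisq` and df = 1.
#' @export
fit_wls <- function(pooled, acov, start = rep(0.1, 5), restarts = 10L) {
  stopifnot(length(pooled) == 6L, all(dim(as.matrix(acov)) == 6L))
  W <- solve(acov)
  W <- (W + t(W)) / 2
  r <- as.numeric(pooled)
  fn <- function(th) cpp_wls_objgrad(th, r, W)$value
  gr <- function(th) cpp_wls_objgrad(th, r, W)$gradient
  opt <- run_nlminb(start, fn, gr, restarts = restarts)
  th <- opt$par
  rj <- cpp_rho_jac(th)
  converged <- opt$convergence == 0 && opt$objective < 1e9 && rj$ok
  chisq <- max(0, opt$objective)
  if (!rj$ok) {
    est <- c(th, NA_real_, NA_real_)
    ses <- rep(NA_real_, 7)
    names(est) <- names(ses) <- .wls_names
    return(new_stage2_result("WLS", est, ses, chisq, df = 1L,
                             converged = FALSE, fmin = opt$objective))
  }
  J <- rj$J
  info <- t(J) %*% W %*% J
  cov5 <- tryCatch(solve(info), error = function(e) NULL)
  psi <- drop(rj$psi)
  K <- derived_psi_jacobian(th)
  est <- c(th, psi)
  names(est) <- .wls_names
  ses <- rep(NA_real_, 7)
  if (!is.null(cov5) && all(diag(cov5) > 0)) {
    ses[1:5] <- sqrt(diag(cov5))
    vpsi <- diag(K %*% cov5 %*% t(K))
    ses[6:7] <- sqrt(pmax(vpsi, 0))
  } else converged <- FALSE
  names(ses) <- .wls_names
  new_stage2_result("WLS", est, ses, chisq, df = 1L,
                    converged = converged, fmin = opt$objective)
}
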