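new_stage1_result <- function(method, pooled, acov, stat, df, p, reject,
                              per_element = NULL, alpha, studies,
                              converged = TRUE, extra = list()) {
  structure(c(list(method = method, pooled = pooled,
                   pooled_matrix = corr_matrix(pooled),
                   acov = acov, stat = stat, df = df, p = p,
                   reject = reject, per_element = per_element,
                   alpha = alpha, k = length(studies$n),
                   N = sum(studies$n), converged = converged),
              extra),
            class = "stage1_result")
}

#' @export
print.stage1_result <- function(x, ...) {
  cat(sprintf("Stage 1 (%s): k = %d studies, total N = %d\n",
              x$method, x$k, x$N))
  cat("pooled correlations:\n")
  print(round(x$pooled, 4))
  if (!is.null(x$per_element)) {
    cat(sprintf("BA1 homogeneity: min p = %.4g (Bonferroni level %g/6), %s\n",
                min(x$per_element$p), x$alpha,
                if (x$reject) "reject" else "retain"))
  } else {
    cat(sprintf("homogeneity %s = %.3f, df = %d, p = %.4g, %s\n",
                if (x$method == "TSSEM") "LR" else "Q", x$stat, x$df, x$p,
                if (x$reject) "reject" else "retain"))
  }
  invisible(x)
}

study_corr_matrix <- function(studies) {
  # k x 6 matrix of per-study correlation vectors
  t(vapply(studies$R, corr_vector, numeric(6)))
}

#' Element-wise homogeneity tests with a Bonferroni-adjusted rule
#'
#' For each of the 6 correlation elements computes a heterogeneity
#' chi-square with k - 1 degrees of freedom and rejects overall
#' homogeneity when the smallest of the 6 p-values falls below
#' `alpha / 6` (the at-least-one rule).  On the z scale the statistic is
#' \eqn{Q = \sum_k (n_k - 3)(z_k - \bar z)^2} with \eqn{\bar z} the
#' (n-3)-weighted mean of the Fisher transforms; on the r scale it is
#' \eqn{Q = \sum_k (n_k - 1)(r_k - \bar r)^2 / (1 - \bar r^2)^2} with
#' \eqn{\bar r} the n-weighted mean.
#'
#' @param studies A [study_set()] with at least 2 studies.
#' @param scale `"r"` or `"z"`; the univariate pooling methods pair
#'   UNIr with `"r"` and UNIz with `"z"`.
#' @param alpha Overall test level.
#' @return A list with the per-element statistics `Q`, common `df`,
#'   p-values `p`, the Bonferroni threshold and the overall `reject`.
#' @export
homogeneity_ba1 <- function(studies, scale = c("r", "z"), alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(inherits(studies, "study_set"))
  k <- length(studies$n)
  if (k < 2) stop("homogeneity test undefined for a single study")
  rmat <- study_corr_matrix(studies)
  n <- studies$n
  if (scale == "z") {
    if (any(abs(rmat) >= 1)) stop("|r| = 1: Fisher transform undefined")
    z <- atanh(rmat)
    w <- n - 3
    zbar <- colSums(w * z) / sum(w)
    Q <- colSums(w * sweep(z, 2, zbar)^2)
  } else {
    rbar <- colSums(n * rmat) / sum(n)
    Q <- colSums((n - 1) * sweep(rmat, 2, rbar)^2) / (1 - rbar^2)^2
  }
  df <- k - 1L
  p <- pchisq(Q, df, lower.tail = FALSE)
  list(Q = Q, df = df, p = p, threshold = alpha / 6,
       reject = min(p) < alpha / 6)
}

#' Univariate pooling of correlations by sample-size weights (UNIr)
#'
#' Pools each correlation element as the n-weighted average of the
#' study correlations (Hunter-Schmidt weighting) and tests homogeneity
#' with the r-scale [homogeneity_ba1()] rule.  No asymptotic covariance
#' of the pooled vector is produced: the univariate route ignores
#' dependencies between correlations.
#'
#' @param studies A [study_set()] with at least 2 studies.
#' @param alpha Homogeneity test level.
#' @param ba1_scale Scale of the element-wise homogeneity statistic.
#' @return A `stage1_result` with `acov = NULL` and per-element tests.
#' @export
pool_unir <- function(studies, alpha = 0.05, ba1_scale = "r") {
  stopifnot(inherits(studies, "study_set"), length(studies$n) >= 2)
  rmat <- study_corr_matrix(studies)
  pooled <- colSums(studies$n * rmat) / sum(studies$n)
  ba1 <- homogeneity_ba1(studies, scale = ba1_scale, alpha = alpha)
  new_stage1_result("UNIr", pooled, acov = NULL,
                    stat = max(ba1$Q), df = ba1$df, p = min(ba1$p),
                    reject = ba1$reject,
                    per_element = data.frame(Q = ba1$Q, df = ba1$df,
                                             p = ba1$p),
                    alpha = alpha, studies = studies)
}

#' Univariate pooling of correlations on the Fisher-z scale (UNIz)
#'
#' Pools each element as the (n-3)-weighted average of the Fisher
#' transforms, back-transformed with tanh (Hedges-Olkin weighting), and
#' tests homogeneity with the z-scale [homogeneity_ba1()] rule.
#'
#' @inheritParams pool_unir
#' @return A `stage1_result` with `acov = NULL` and per-element tests.
#' @export
pool_uniz <- function(studies, alpha = 0.05, ba1_scale = "z") {
  stopifnot(inherits(studies, "study_set"), length(studies$n) >= 2)
  rmat <- study_corr_matrix(studies)
  if (any(abs(rmat) >= 1)) stop("|r| = 1: Fisher transform undefined")
  if (any(studies$n <= 3)) stop("all studies must have n > 3")
  w <- studies$n - 3
  zbar <- colSums(w * atanh(rmat)) / sum(w)
  pooled <- tanh(zbar)
  names(pooled) <- .vec_names
  ba1 <- homogeneity_ba1(studies, scale = ba1_scale, alpha = alpha)
  new_stage1_result("UNIz", pooled, acov = NULL,
                    stat = max(ba1$Q), df = ba1$df, p = min(ba1$p),
                    reject = ba1$reject,
                    per_element = data.frame(Q = ba1$Q, df = ba1$df,
                                             p = ba1$p),
                    alpha = alpha, studies = studies)
}

#' Olkin-Siotani asymptotic covariance of sample correlations
#'
#' Large-sample covariance matrix of the 6 sample correlations of a
#' 4-variable normal sample of size n, evaluated at population
#' correlations `rho`.  The entry for element pairs (a,b) and (c,d) is
#' \deqn{[\tfrac12 \rho_{ab}\rho_{cd}(\rho_{ac}^2+\rho_{ad}^2+\rho_{bc}^2
#'  +\rho_{bd}^2) + \rho_{ac}\rho_{bd} + \rho_{ad}\rho_{bc}
#'  - (\rho_{ab}\rho_{ac}\rho_{ad} + \rho_{ab}\rho_{bc}\rho_{bd}
#'  + \rho_{cd}\rho_{ac}\rho_{bc} + \rho_{cd}\rho_{ad}\rho_{bd})]/n,}
#' whose diagonal reduces to \eqn{(1-\rho_{ab}^2)^2/n}.
#'
#' @param rho Length-6 correlation vector (element order of
#'   [corr_vector()]) corresponding to a positive definite matrix.
#' @param n Sample size (> 4).
#' @return 6x6 symmetric covariance matrix.
#' @export
olkin_siotani_acov <- function(rho, n) {
  stopifnot(length(rho) == 6L, n > 4)
  os_acov_shape(rho) / n
}

# unit-sample-size (n = 1) shape of the Olkin-Siotani covariance
os_acov_shape <- function(rho) {
  stopifnot(length(rho) == 6L)
  P <- corr_matrix(rho)
  if (any(eigen(P, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'rho' does not correspond to a positive definite matrix")
  V <- matrix(0, 6, 6)
  for (m1 in 1:6) {
    a <- .vec_idx[m1, 1L]; b <- .vec_idx[m1, 2L]
    for (m2 in m1:6) {
      cc <- .vec_idx[m2, 1L]; d <- .vec_idx[m2, 2L]
      v <- 0.5 * P[a, b] * P[cc, d] *
             (P[a, cc]^2 + P[a, d]^2 + P[b, cc]^2 + P[b, d]^2) +
           P[a, cc] * P[b, d] + P[a, d] * P[b, cc] -
           (P[a, b] * (P[a, cc] * P[a, d] + P[b, cc] * P[b, d]) +
            P[cc, d] * (P[a, cc] * P[b, cc] + P[a, d] * P[b, d]))
      V[m1, m2] <- V[m2, m1] <- v
    }
  }
  dimnames(V) <- list(.vec_names, .vec_names)
  V
}

#' Modified GLS pooling of correlation matrices
#'
#' Generalized least squares pooling of the stacked study correlation
#' vectors, with per-study weight matrices from the Olkin-Siotani
#' covariance.  The "modified" form evaluates every weight matrix at a
#' single common plug-in correlation vector (the UNIr pooled vector by
#' default) rather than at the study's own correlations; the
#' traditional study-specific plug-in is available via
#' `weights = "study"`.  The homogeneity statistic is
#' \eqn{Q_{GLS} = \sum_i (r_i - \hat\rho)' \Psi_i^{-1} (r_i - \hat\rho)}
#' with 6(k - 1) degrees of freedom.
#'
#' @param studies A [study_set()] with at least 2 studies.
#' @param alpha Homogeneity test level.
#' @param weights `"pooled"` (modified GLS) or `"study"` (traditional).
#' @param plugin Pooled plug-in used when `weights = "pooled"`:
#'   `"unir"` (n-weighted mean) or `"uniz"` (back-transformed z mean).
#' @return A `stage1_result` with the pooled vector, its asymptotic
#'   covariance `acov`, and the Q_GLS test.
#' @export
pool_mgls <- function(studies, alpha = 0.05,
                      weights = c("pooled", "study"),
                      plugin = c("unir", "uniz")) {
  weights <- match.arg(weights)
  plugin <- match.arg(plugin)
  stopifnot(inherits(studies, "study_set"), length(studies$n) >= 2)
  rmat <- study_corr_matrix(studies)
  n <- studies$n
  k <- length(n)
  if (weights == "pooled") {
    plug <- if (plugin == "unir") colSums(n * rmat) / sum(n)
            else tanh(colSums((n - 3) * atanh(rmat)) / sum(n - 3))
    V1 <- os_acov_shape(plug)           # common shape, scaled by 1/n_i
    W1 <- solve(V1)
    Wi <- lapply(seq_len(k), function(i) n[i] * W1)
  } else {
    Wi <- lapply(seq_len(k), function(i) {
      Vi <- olkin_siotani_acov(rmat[i, ], n[i])
      tryCatch(solve(Vi), error = function(e)
        stop(sprintf("singular weight matrix for study %d", i)))
    })
  }
  Wsum <- Reduce(`+`, Wi)
  rhs <- Reduce(`+`, lapply(seq_len(k), function(i) Wi[[i]] %*% rmat[i, ]))
  acov <- solve(Wsum)
  pooled <- drop(acov %*% rhs)
  names(pooled) <- .vec_names
  Q <- sum(vapply(seq_len(k), function(i) {
    e <- rmat[i, ] - pooled
    drop(e %*% Wi[[i]] %*% e)
  }, numeric(1)))
  df <- 6L * (k - 1L)
  p <- pchisq(Q, df, lower.tail = FALSE)
  new_stage1_result("MGLS", pooled, acov = (acov + t(acov)) / 2,
                    stat = Q, df = df, p = p, reject = p < alpha,
                    alpha = alpha, studies = studies)
}

#' TSSEM stage-1 pooling by constrained multigroup likelihood
#'
#' Pools the k studies by maximizing the multigroup normal likelihood
#' under the constraint \eqn{\Sigma_g = D_g R D_g}: a common 6-parameter
#' correlation matrix R with group-specific positive diagonal scalings
#' \eqn{D_g}.  The discrepancy
#' \deqn{F = \sum_g (n_g/N)[\ln|\Sigma_g| - \ln|S_g|
#'        + tr(S_g \Sigma_g^{-1}) - 4]}
#' is minimized by a quasi-Newton method with analytic gradients,
#' starting from \eqn{D_g = I} and R at the UNIr pooled matrix.  The
#' homogeneity statistic is the likelihood ratio against the saturated
#' model (each group its own matrix), \eqn{LR = N F_{min}}, with
#' 6(k - 1) degrees of freedom.  The asymptotic covariance of the pooled
#' correlations is the R-block inverse of the expected information.
#'
#' @param studies A [study_set()] with at least 2 studies, each sample
#'   correlation matrix positive definite.
#' @param alpha Homogeneity test level.
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap of the optimizer.
#' @return A `stage1_result`; `converged` is `FALSE` when the optimizer
#'   failed (such replicates are counted separately by the harness).
#' @export
pool_tssem <- function(studies, alpha = 0.05, tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(studies, "study_set"), length(studies$n) >= 2)
  n <- as.numeric(studies$n)
  k <- length(n)
  S <- array(unlist(studies$R), dim = c(4, 4, k))
  rmat <- study_corr_matrix(studies)
  start_rho <- colSums(n * rmat) / sum(n)
  # guard: shrink toward zero if the start matrix is not PD
  while (min(eigen(corr_matrix(start_rho), symmetric = TRUE,
                   only.values = TRUE)$values) <= 1e-8)
    start_rho <- 0.9 * start_rho
  par0 <- c(start_rho, rep(0, 4 * k))

  fn <- function(p) cpp_tssem_objgrad(p, S, n)$value
  gr <- function(p) cpp_tssem_objgrad(p, S, n)$gradient
  opt <- nlminb(par0, fn, gr,
                control = list(rel.tol = tol, iter.max = max_iter,
                               eval.max = 2L * max_iter))
  gnorm <- max(abs(gr(opt$par)))
  converged <- (opt$convergence == 0 || gnorm < 1e-4) &&
               opt$objective < 1e9
  pooled <- opt$par[1:6]
  names(pooled) <- .vec_names
  stat <- sum(n) * opt$objective
  df <- 6L * (k - 1L)
  p <- pchisq(stat, df, lower.tail = FALSE)
  acov <- tryCatch(cpp_tssem_acov(opt$par, n), error = function(e) NULL)
  if (is.null(acov)) converged <- FALSE
  new_stage1_result("TSSEM", pooled, acov = acov,
                    stat = stat, df = df, p = p, reject = p < alpha,
                    alpha = alpha, studies = studies,
                    converged = converged,
                    extra = list(scale = exp(opt$par[-(1:6)]),
                                 objective = opt$objective,
                                 iterations = opt$iterations))
}
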