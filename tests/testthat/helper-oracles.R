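# Independent oracle implementations used only by the tests.  These are
# written from the textbook scalar formulas / generic optimizers, on
# purpose not sharing code with the package internals they check.

# Implied covariance of the recursive model by scalar substitution:
# Y1 = g11 X1 + g12 X2 + z1 ;  Y2 = b21 Y1 + g21 X1 + g22 X2 + z2.
oracle_implied_cov <- function(g11, g12, g21, g22, b21,
                               ph11, ph22, ph12, ps1, ps2) {
  vY1  <- g11^2 * ph11 + g12^2 * ph22 + 2 * g11 * g12 * ph12 + ps1
  cY1X1 <- g11 * ph11 + g12 * ph12
  cY1X2 <- g11 * ph12 + g12 * ph22
  c1 <- b21 * g11 + g21
  c2 <- b21 * g12 + g22
  vY2 <- c1^2 * ph11 + c2^2 * ph22 + 2 * c1 * c2 * ph12 +
    b21^2 * ps1 + ps2
  cY2X1 <- c1 * ph11 + c2 * ph12
  cY2X2 <- c1 * ph12 + c2 * ph22
  cY1Y2 <- b21 * vY1 + g21 * cY1X1 + g22 * cY1X2
  m <- rbind(c(vY1,   cY1Y2, cY1X1, cY1X2),
             c(cY1Y2, vY2,   cY2X1, cY2X2),
             c(cY1X1, cY2X1, ph11,  ph12),
             c(cY1X2, cY2X2, ph12,  ph22))
  dimnames(m) <- list(c("Y1", "Y2", "X1", "X2"), c("Y1", "Y2", "X1", "X2"))
  m
}

# Brute-force structural simulation: generate data by substituting the
# structural equations observation by observation.
oracle_simulate_cov <- function(g11, g12, g21, g22, b21,
                                ph11, ph22, ph12, ps1, ps2, n) {
  Phi <- rbind(c(ph11, ph12), c(ph12, ph22))
  X <- matrix(rnorm(2 * n), n, 2) %*% chol(Phi)
  z1 <- rnorm(n, sd = sqrt(ps1))
  z2 <- rnorm(n, sd = sqrt(ps2))
  Y1 <- g11 * X[, 1] + g12 * X[, 2] + z1
  Y2 <- b21 * Y1 + g21 * X[, 1] + g22 * X[, 2] + z2
  stats::cov(cbind(Y1, Y2, X[, 1], X[, 2]))
}

# Random admissible theta5 for the standardized model.
random_theta5 <- function() {
  repeat {
    th <- c(runif(3, -0.55, 0.55), runif(1, -0.55, 0.55),
            runif(1, -0.45, 0.45))
    ps <- tryCatch(derived_psi(th), error = function(e) NULL)
    if (!is.null(ps) && all(ps > 0.05)) return(th)
  }
}

# Independent multigroup-ML discrepancy for the common-correlation
# constraint, written with base determinant/solve calls.
oracle_tssem_F <- function(par, Rlist, n) {
  rho <- par[1:6]
  R <- diag(4)
  idx <- rbind(c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(4, 2), c(4, 3))
  for (m in 1:6) { R[idx[m, 1], idx[m, 2]] <- rho[m]
                   R[idx[m, 2], idx[m, 1]] <- rho[m] }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(1e10)
  N <- sum(n)
  Ftot <- 0
  for (g in seq_along(n)) {
    d <- exp(par[6 + 4 * (g - 1) + 1:4])
    Sg <- Rlist[[g]]
    Sigma <- diag(d) %*% R %*% diag(d)
    Ftot <- Ftot + (n[g] / N) *
      (determinant(Sigma)$modulus - determinant(Sg)$modulus +
         sum(diag(Sg %*% solve(Sigma))) - 4)
  }
  as.numeric(Ftot)
}

# Independent ML discrepancy for the stage-2 fit.
oracle_ml_F <- function(theta, S) {
  Sigma <- oracle_implied_cov(theta[1], theta[2], theta[3], 0, theta[4],
                              theta[5], theta[6], theta[7],
                              theta[8], theta[9])
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) return(1e10)
  as.numeric(determinant(Sigma)$modulus - determinant(S)$modulus +
               sum(diag(S %*% solve(Sigma))) - 4)
}

# Independent WLS discrepancy over theta5 (rho(theta) via the exported
# correlation-structure map, quadratic form assembled here).
oracle_wls_F <- function(theta, r, W) {
  rho <- tryCatch(implied_corr_vector(theta), error = function(e) NULL)
  if (is.null(rho)) return(1e10)
  e <- r - rho
  as.numeric(e %*% W %*% e)
}

# A small synthetic study set with heterogeneous correlation values.
make_studyset <- function(k = 3, n = c(40, 60, 90), seed = 42) {
  set.seed(seed)
  R <- lapply(seq_len(k), function(i) simulate_study(n[i], sigma_pop()))
  study_set(n[seq_len(k)], R)
}
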