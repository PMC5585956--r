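test_that("implied covariance reproduces the population matrix from the block formula", {
  S <- implied_covariance(default_path_params())
  expect_equal(unname(diag(S)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(corr_vector(S)),
               c(0.65, 0.50, 0.58, 0.55, 0.35, 0.20), tolerance = 1e-12)
  expect_equal(S, t(S))
})

test_that("implied covariance of a null model is the identity", {
  p <- path_params(gamma = matrix(0, 2, 2), beta = matrix(0, 2, 2),
                   phi = diag(2), psi = diag(2))
  expect_equal(unname(implied_covariance(p)), diag(4))
})

test_that("implied covariance agrees with scalar-substitution and simulation oracles", {
  set.seed(101)
  for (i in 1:25) {
    g <- runif(3, -0.6, 0.6); b <- runif(1, -0.6, 0.6)
    ph12 <- runif(1, -0.5, 0.5)
    ps <- runif(2, 0.3, 1.5)
    p <- path_params(gamma = rbind(g[1:2], c(g[3], 0)),
                     beta = rbind(c(0, 0), c(b, 0)),
                     phi = rbind(c(1, ph12), c(ph12, 1)),
                     psi = diag(ps))
    expect_equal(implied_covariance(p),
                 oracle_implied_cov(g[1], g[2], g[3], 0, b,
                                    1, 1, ph12, ps[1], ps[2]),
                 tolerance = 1e-12)
  }
  # one structural simulation at large n
  set.seed(7)
  emp <- oracle_simulate_cov(0.4, 0.5, 0.3, 0, 0.5, 1, 1, 0.2,
                             0.51, 0.51, n = 2e5)
  expect_lt(max(abs(emp - implied_covariance(default_path_params()))), 0.012)
})

test_that("non-recursive specifications are rejected", {
  expect_error(path_params(gamma = matrix(0, 2, 2),
                           beta = rbind(c(0, 0.5), c(0.5, 0)),
                           phi = diag(2), psi = diag(2)),
               "lower triangular")
})

test_that("correlation vector and matrix round-trip losslessly", {
  set.seed(3)
  for (i in 1:20) {
    v <- corr_vector(simulate_study(40, sigma_pop()))
    expect_identical(unname(corr_vector(corr_matrix(v))), unname(v))
  }
  expect_equal(corr_matrix(corr_vector(sigma_pop())), sigma_pop())
})

test_that("the alternative population matrix holds the stated constants and is PD", {
  Sp <- sigma_prime()
  expect_identical(unname(corr_vector(Sp)),
                   c(0.45, 0.30, 0.40, 0.35, 0.19, 0.15))
  expect_gt(min(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("derived disturbance variances standardize the model", {
  expect_equal(unname(derived_psi(c(0.4, 0.5, 0.3, 0.5, 0.2))),
               c(0.51, 0.51), tolerance = 1e-12)
  expect_equal(unname(derived_psi(rep(0, 5))), c(1, 1))
  expect_error(derived_psi(c(0.9, 0.9, 0, 0, 0.5)), "inadmissible")
  set.seed(11)
  for (i in 1:50) {
    th <- random_theta5()
    ps <- derived_psi(th)
    p <- path_params(gamma = rbind(th[1:2], c(th[3], 0)),
                     beta = rbind(c(0, 0), c(th[4], 0)),
                     phi = rbind(c(1, th[5]), c(th[5], 1)),
                     psi = diag(unname(ps)))
    expect_equal(unname(diag(implied_covariance(p))), rep(1, 4),
                 tolerance = 1e-10)
  }
})

test_that("the correlation-structure map matches the printed values and the scalar oracle", {
  expect_equal(unname(implied_corr_vector(c(0.4, 0.5, 0.3, 0.5, 0.2))),
               c(0.65, 0.50, 0.58, 0.55, 0.35, 0.20), tolerance = 1e-12)
  expect_equal(unname(implied_corr_vector(rep(0, 5))), rep(0, 6))
  set.seed(19)
  for (i in 1:200) {
    th <- random_theta5()
    ps <- derived_psi(th)
    o <- oracle_implied_cov(th[1], th[2], th[3], 0, th[4], 1, 1, th[5],
                            ps[1], ps[2])
    expect_equal(unname(implied_corr_vector(th)),
                 unname(o[cbind(c(2, 3, 4, 3, 4, 4), c(1, 1, 1, 2, 2, 3))]),
                 tolerance = 1e-10)
  }
})

test_that("analytic Jacobian of the derived variances matches finite differences", {
  set.seed(23)
  h <- 1e-6
  for (i in 1:10) {
    th <- random_theta5()
    K <- masemsim:::derived_psi_jacobian(th)
    for (q in 1:5) {
      e <- numeric(5); e[q] <- h
      num <- (derived_psi(th + e) - derived_psi(th - e)) / (2 * h)
      expect_equal(unname(K[, q]), unname(num), tolerance = 1e-5)
    }
  }
})
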