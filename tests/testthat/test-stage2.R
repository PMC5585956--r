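test_that("ML fit recovers exact parameters from the population matrix", {
  fit <- fit_ml(sigma_pop(), 500)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(0.4, 0.5, 0.3, 0.5, 1, 1, 0.2, 0.51, 0.51),
               tolerance = 1e-5)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$df, 1L)
  expect_true(all(is.finite(fit$ses)))
})

test_that("ML fit of the identity matrix gives zero paths and perfect fit", {
  fit <- fit_ml(diag(4), 200)
  expect_lt(max(abs(fit$estimates[c(1:4, 7)])), 1e-5)
  expect_lt(fit$chisq, 1e-8)
})

test_that("ML optimum matches a 50-random-start search on an independent objective", {
  set.seed(61)
  S <- simulate_study(150, sigma_pop())
  fit <- fit_ml(S, 150)
  best <- Inf
  for (s in 1:50) {
    start <- c(runif(4, -0.6, 0.6), runif(2, 0.5, 1.5),
               runif(1, -0.4, 0.4), runif(2, 0.3, 1.3))
    o <- tryCatch(
      stats::optim(start, oracle_ml_F, S = S, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o)) best <- min(best, o$value)
  }
  expect_equal(fit$fmin, best, tolerance = 1e-6)
})

test_that("ML standard errors shrink as 1/sqrt(N)", {
  f1 <- fit_ml(sigma_pop(), 401)
  f2 <- fit_ml(sigma_pop(), 1601)
  expect_equal(unname(f1$ses / f2$ses), rep(2, 9), tolerance = 0.01)
})

test_that("WLS fit recovers exact parameters and derived variances", {
  rho <- corr_vector(sigma_pop())
  V <- olkin_siotani_acov(rho, 500)
  fit <- fit_wls(rho, V)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(0.4, 0.5, 0.3, 0.5, 0.2, 0.51, 0.51), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-8)
  expect_true(all(is.finite(fit$ses)))
})

test_that("WLS estimates are invariant to weight scale while chisq scales", {
  set.seed(71)
  r <- corr_vector(simulate_study(200, sigma_pop()))
  f1 <- fit_wls(r, diag(6))
  f5 <- fit_wls(r, 5 * diag(6))
  expect_equal(f1$estimates, f5$estimates, tolerance = 1e-6)
  expect_equal(f1$chisq, 5 * f5$chisq, tolerance = 1e-6)
})

test_that("WLS optimum matches a multi-start search on an independent objective", {
  set.seed(81)
  ss <- make_studyset(k = 5, n = rep(100, 5), seed = 83)
  s1 <- pool_mgls(ss)
  fit <- fit_wls(s1$pooled, s1$acov)
  W <- solve(s1$acov)
  best <- Inf
  for (s in 1:20) {
    o <- tryCatch(
      stats::optim(random_theta5(), oracle_wls_F, r = s1$pooled, W = W,
                   method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(o)) best <- min(best, o$value)
  }
  expect_equal(fit$chisq, best, tolerance = 1e-5)
})

test_that("perfect-fit recovery holds across random admissible parameter sets", {
  set.seed(91)
  for (i in 1:10) {
    th <- random_theta5()
    rho <- implied_corr_vector(th)
    # WLS route with an arbitrary PD weight
    V <- olkin_siotani_acov(0.8 * rho, 300)
    fw <- fit_wls(rho, V)
    expect_lt(fw$chisq, 1e-7)
    expect_equal(unname(fw$estimates[1:5]), th, tolerance = 1e-4)
    # ML route on the exactly implied matrix
    fm <- fit_ml(corr_matrix(rho), 250)
    expect_lt(fm$chisq, 1e-6)
    expect_equal(unname(fm$estimates[c(1:4, 7)]), th, tolerance = 1e-3)
  }
})

test_that("compiled gradients agree with finite differences of the objectives", {
  set.seed(95)
  S <- simulate_study(120, sigma_pop())
  th9 <- c(0.3, 0.4, 0.2, 0.4, 1.1, 0.9, 0.15, 0.8, 0.7)
  og <- masemsim:::cpp_ml_objgrad(th9, S)
  h <- 1e-6
  num <- vapply(1:9, function(q) {
    e <- numeric(9); e[q] <- h
    (masemsim:::cpp_ml_objgrad(th9 + e, S)$value -
       masemsim:::cpp_ml_objgrad(th9 - e, S)$value) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(og$gradient), num, tolerance = 1e-5)

  ss <- make_studyset(k = 3, n = c(40, 60, 90), seed = 97)
  Scube <- array(unlist(ss$R), dim = c(4, 4, 3))
  par <- c(corr_vector(sigma_pop()) * 0.9, rnorm(12, 0, 0.05))
  og <- masemsim:::cpp_tssem_objgrad(par, Scube, ss$n)
  num <- vapply(seq_along(par), function(q) {
    e <- numeric(length(par)); e[q] <- h
    (masemsim:::cpp_tssem_objgrad(par + e, Scube, ss$n)$value -
       masemsim:::cpp_tssem_objgrad(par - e, Scube, ss$n)$value) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(og$gradient), num, tolerance = 1e-5)

  W <- solve(olkin_siotani_acov(corr_vector(sigma_pop()), 200))
  th5 <- c(0.3, 0.4, 0.2, 0.4, 0.15)
  r <- corr_vector(sigma_pop())
  og <- masemsim:::cpp_wls_objgrad(th5, r, W)
  num <- vapply(1:5, function(q) {
    e <- numeric(5); e[q] <- h
    (masemsim:::cpp_wls_objgrad(th5 + e, r, W)$value -
       masemsim:::cpp_wls_objgrad(th5 - e, r, W)$value) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(og$gradient), num, tolerance = 1e-5)
})
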