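# study sets with prescribed single-element values, rest held equal
set_with_element <- function(ns, vals, elem = 1, base = 0.3) {
  R <- lapply(vals, function(v) {
    vec <- rep(base, 6)
    vec[elem] <- v
    corr_matrix(vec)
  })
  study_set(ns, R)
}

test_that("UNIr pools by sample-size weighted means", {
  s <- set_with_element(c(100, 300), c(0.5, 0.7))
  expect_equal(unname(pool_unir(s)$pooled[1]), 0.65)  # (0.5*100+0.7*300)/400
  # identical matrices: pooled equals the input
  s2 <- study_set(c(40, 80), list(sigma_pop(), sigma_pop()))
  expect_equal(pool_unir(s2)$pooled, corr_vector(sigma_pop()))
  # equal n: unweighted mean
  s3 <- set_with_element(c(50, 50, 50), c(0.2, 0.4, 0.6))
  expect_equal(unname(pool_unir(s3)$pooled[1]), 0.4)
})

test_that("UNIz pools on the Fisher-z scale and stays within the study range", {
  s <- set_with_element(c(103, 103), c(0.0, 0.6))
  expect_equal(unname(pool_uniz(s)$pooled[1]), tanh(atanh(0.6) / 2),
               tolerance = 1e-12)
  expect_equal(unname(pool_uniz(s)$pooled[1]), 1 / 3, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:10) {
    ss <- make_studyset(seed = i)
    pooled <- pool_uniz(ss)$pooled
    rmat <- sapply(ss$R, corr_vector)
    expect_true(all(pooled >= apply(rmat, 1, min) - 1e-12))
    expect_true(all(pooled <= apply(rmat, 1, max) + 1e-12))
  }
})

test_that("BA1 element tests match the closed-form Q and reject only on true spread", {
  # all studies identical: every Q = 0, no rejection
  s0 <- study_set(c(50, 60), list(sigma_pop(), sigma_pop()))
  ba <- homogeneity_ba1(s0, scale = "z")
  expect_equal(unname(ba$Q), rep(0, 6), tolerance = 1e-12)
  expect_false(ba$reject)
  # z-scale hand computation: k = 2, n = (103, 103), z = (0, 0.4)
  s <- set_with_element(c(103, 103), tanh(c(0, 0.4)))
  ba <- homogeneity_ba1(s, scale = "z")
  expect_equal(unname(ba$Q[1]), 8.0, tolerance = 1e-10)
  expect_equal(ba$df, 1L)
  # r-scale statistic: (n-1)-weighted squared deviations over (1-rbar^2)^2
  sr <- set_with_element(c(41, 61), c(0.2, 0.5))
  rbar <- (41 * 0.2 + 61 * 0.5) / 102  # n-weighted pooled value
  Q_hand <- (40 * (0.2 - rbar)^2 + 60 * (0.5 - rbar)^2) / (1 - rbar^2)^2
  expect_equal(unname(homogeneity_ba1(sr, scale = "r")$Q[1]), Q_hand,
               tolerance = 1e-12)
})

test_that("Olkin-Siotani covariance matches its closed forms and a Monte Carlo oracle", {
  # independence: diag(1/n), zero off-diagonals
  V0 <- olkin_siotani_acov(rep(0, 6), 50)
  expect_equal(unname(V0), diag(6) / 50, tolerance = 1e-12)
  # printed diagonal value for rho = 0.65, n = 100
  V <- olkin_siotani_acov(corr_vector(sigma_pop()), 100)
  expect_equal(unname(V[1, 1]), (1 - 0.65^2)^2 / 100, tolerance = 1e-12)
  expect_equal(unname(V[1, 1]), 0.0033351, tolerance = 1e-4)
  # MC oracle: empirical covariance of sample correlations
  set.seed(77)
  n <- 300
  reps <- 15000
  draws <- t(replicate(reps, corr_vector(simulate_study(n, sigma_pop()))))
  emp <- stats::cov(draws) * n
  expect_lt(max(abs(emp - V * 100)), 0.08)  # both on the n = 1 scale
})

test_that("MGLS solves the stacked GLS normal equations and reduces to UNIr with common weights", {
  ss <- make_studyset(k = 4, n = c(30, 50, 80, 120), seed = 9)
  # traditional (study-specific) weights against an explicitly stacked GLS
  fit <- pool_mgls(ss, weights = "study")
  rmat <- sapply(ss$R, corr_vector)
  Wi <- lapply(seq_along(ss$n), function(i)
    solve(olkin_siotani_acov(rmat[, i], ss$n[i])))
  XtWX <- Reduce(`+`, Wi)
  XtWr <- Reduce(`+`, lapply(seq_along(Wi), function(i) Wi[[i]] %*% rmat[, i]))
  expect_equal(unname(fit$pooled), unname(drop(solve(XtWX, XtWr))),
               tolerance = 1e-10)
  # modified form: pooled estimate coincides with UNIr pooling
  expect_equal(pool_mgls(ss)$pooled, pool_unir(ss)$pooled, tolerance = 1e-10)
  # identical studies of equal n: pooled equals the common matrix, Q = 0
  s0 <- study_set(c(50, 50), list(sigma_pop(), sigma_pop()))
  f0 <- pool_mgls(s0)
  expect_equal(f0$pooled, corr_vector(sigma_pop()))
  expect_equal(f0$stat, 0, tolerance = 1e-16)
  expect_equal(f0$df, 6L)
})

test_that("Q_GLS and the TSSEM likelihood ratio are invariant to study order", {
  ss <- make_studyset(k = 4, n = c(30, 50, 80, 120), seed = 13)
  perm <- c(3, 1, 4, 2)
  ssp <- study_set(ss$n[perm], ss$R[perm], ss$labels[perm])
  expect_equal(pool_mgls(ss)$stat, pool_mgls(ssp)$stat, tolerance = 1e-8)
  expect_equal(pool_tssem(ss)$stat, pool_tssem(ssp)$stat, tolerance = 1e-5)
})

test_that("TSSEM recovers a common matrix exactly and matches a multi-start oracle", {
  s0 <- study_set(c(50, 80, 60),
                  list(sigma_pop(), sigma_pop(), sigma_pop()))
  f0 <- pool_tssem(s0)
  expect_true(f0$converged)
  expect_equal(f0$pooled, corr_vector(sigma_pop()), tolerance = 1e-6)
  expect_lt(abs(f0$stat), 1e-4)
  # k = 2: minimized discrepancy against 20 random starts of a generic
  # quasi-Newton run on an independently coded objective
  ss <- make_studyset(k = 2, n = c(40, 70), seed = 21)
  fit <- pool_tssem(ss)
  set.seed(33)
  best <- Inf
  for (s in 1:20) {
    start <- c(corr_vector(sigma_pop()) * runif(6, 0.5, 1.1),
               rnorm(8, 0, 0.1))
    o <- tryCatch(
      stats::optim(start, oracle_tssem_F, Rlist = ss$R, n = ss$n,
                   method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o)) best <- min(best, o$value)
  }
  expect_equal(sum(ss$n) * best, fit$stat, tolerance = 1e-4)
  # acov sanity: symmetric PD, shrinking with sample size
  expect_equal(fit$acov, t(fit$acov), tolerance = 1e-10)
  expect_gt(min(eigen(fit$acov, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  ss2 <- study_set(ss$n * 4, ss$R)
  expect_equal(pool_tssem(ss2)$acov, fit$acov / 4, tolerance = 0.05 * max(fit$acov))
})

test_that("all four pooling methods are consistent for the population vector", {
  cfg <- sim_cell_config(3, 10000, "E", replications = 15, seed = 55)
  truth <- corr_vector(sigma_pop())
  for (m in c("unir", "uniz", "mgls", "tssem")) {
    pooled <- sapply(1:15, function(r)
      masemsim:::stage1_fun(m)(simulate_meta(cfg, r))$pooled)
    expect_lt(max(abs(rowMeans(pooled) - truth)), 0.005)
  }
})
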