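# Core state space machinery: simulator, exact filter/smoother, EM.

test_that("zero-noise simulation reduces to the deterministic recursion", {
  m <- 2; l <- 3
  F <- matrix(c(0.5, 0.1, -0.2, 0.8), 2, 2)
  H <- matrix(c(1, 0, 2, 0, 1, -1), 3, 2)
  p <- ssm_params(F = F, H = H, Q = matrix(0, m, m), R = matrix(0, l, l),
                  mu0 = c(1, -1), Sigma0 = matrix(0, m, m))
  sim <- simulate_ssm(p, T = 6, seed = 3)
  x <- c(1, -1)
  for (t in 1:6) {
    if (t > 1) x <- F %*% x
    expect_equal(unname(sim$data$values[, t]), as.numeric(H %*% x), tolerance = 1e-12)
  }
})

test_that("white-noise observation model yields i.i.d. standard normals", {
  p <- ssm_params(F = matrix(0), H = matrix(1), Q = matrix(1), R = matrix(0),
                  mu0 = 0, Sigma0 = matrix(1))
  sim <- simulate_ssm(p, T = 10000, seed = 11)
  y <- as.numeric(sim$data$values)
  expect_lt(abs(var(y) - 1), 0.05)
  expect_lt(abs(mean(y)), 0.05)
})

test_that("simulation honours shape contracts and seeded determinism", {
  p <- rand_params(2, 4, seed = 5)
  s1 <- simulate_ssm(p, T = 1, seed = 9)
  expect_equal(ncol(s1$data$values), 1L)
  expect_equal(dim(s1$states), c(2L, 1L))
  a <- simulate_ssm(p, T = 12, seed = 4)
  b <- simulate_ssm(p, T = 12, seed = 4)
  expect_identical(a$data$values, b$data$values)
  expect_false(identical(a$data$values, simulate_ssm(p, T = 12, seed = 5)$data$values))
})

test_that("non-PSD covariance input is rejected", {
  expect_error(ssm_params(F = matrix(0.5), H = matrix(1), Q = matrix(-1),
                          R = matrix(0.1), mu0 = 0, Sigma0 = matrix(1)),
               "positive semi-definite")
})

test_that("single-step filter equals the closed-form Gaussian density", {
  p <- rand_params(2, 3, seed = 7)
  y1 <- c(0.3, -1.2, 0.5)
  d <- expression_dataset(matrix(y1, 3, 1))
  fs <- kalman_filter_smoother(p, d)
  S <- p$H %*% p$Sigma0 %*% t(p$H) + p$R
  e <- y1 - as.numeric(p$H %*% p$mu0)
  ll <- -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                  sum(e * solve(S, e)))
  expect_equal(fs$loglik, as.numeric(ll), tolerance = 1e-10)
  expect_equal(fs$smoothed_means, fs$filtered_means, tolerance = 1e-12)
})

test_that("filter/smoother matches the stacked joint-Gaussian oracle", {
  p <- rand_params(2, 3, seed = 0)
  sim <- simulate_ssm(p, T = 4, seed = 0)
  fs <- kalman_filter_smoother(p, sim$data)
  or <- joint_gaussian_oracle(p, sim$data$values)
  expect_equal(fs$loglik, or$loglik, tolerance = 1e-8)
  expect_equal(fs$smoothed_means, or$smoothed_means, tolerance = 1e-6)
  # smoothed and lag-one covariances against conditional-covariance blocks
  for (t in 1:4) {
    expect_equal(fs$smoothed_covs[, , t],
                 or$cond_cov[or$blk(t), or$blk(t)], tolerance = 1e-6)
  }
  for (t in 1:3) {
    expect_equal(fs$lag_one_covs[, , t],
                 or$cond_cov[or$blk(t + 1), or$blk(t)], tolerance = 1e-6)
  }
})

test_that("filter/smoother exactness holds across random small instances", {
  shapes <- list(c(1, 2, 5), c(2, 3, 4), c(3, 4, 5), c(1, 1, 8), c(2, 2, 10),
                 c(3, 2, 6), c(2, 4, 7), c(1, 3, 12))
  for (s in shapes) {
    p <- rand_params(s[1], s[2], seed = 100 + s[1] * 10 + s[3])
    sim <- simulate_ssm(p, T = s[3], seed = 200 + s[3])
    fs <- kalman_filter_smoother(p, sim$data)
    or <- joint_gaussian_oracle(p, sim$data$values)
    expect_equal(fs$loglik, or$loglik, tolerance = 1e-6)
    expect_equal(fs$smoothed_means, or$smoothed_means, tolerance = 1e-6)
  }
})

test_that("smoothed covariances are symmetric PSD within tolerance", {
  p <- rand_params(3, 4, seed = 21)
  sim <- simulate_ssm(p, T = 9, seed = 22)
  fs <- kalman_filter_smoother(p, sim$data)
  for (t in 1:9) {
    M <- fs$smoothed_covs[, , t]
    expect_lt(max(abs(M - t(M))), 1e-8)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("log-likelihood is invariant under orthogonal latent rotation", {
  p <- rand_params(3, 4, seed = 31)
  sim <- simulate_ssm(p, T = 7, seed = 32)
  set.seed(33)
  O <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  pr <- rotate_params(p, O)
  ll1 <- kalman_filter_smoother(p, sim$data)$loglik
  ll2 <- kalman_filter_smoother(pr, sim$data)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("EM log-likelihood traces are non-decreasing", {
  for (s in 1:6) {
    p <- rand_params(2, 5, seed = 40 + s)
    sim <- simulate_ssm(p, T = 25, seed = 50 + s)
    fit <- em_fit(sim$data, m = 2, max_iter = 40, tol = 1e-10)
    expect_gte(min(diff(fit$trace$logliks)), -1e-6)
  }
})

test_that("one EM iteration reproduces the closed-form M-step formulas", {
  set.seed(0)
  d <- expression_dataset(matrix(rnorm(10), 2, 5))
  init <- em_init(expression_dataset(d$values - rowMeans(d$values)), m = 1)
  fit <- em_fit(d, m = 1, max_iter = 1, tol = 0, init = init)
  Yc <- d$values - rowMeans(d$values)
  fs <- kalman_filter_smoother(init, expression_dataset(Yc))
  or <- mstep_oracle(init, fs, Yc)
  expect_equal(unname(fit$params$F), unname(or$F), tolerance = 1e-8)
  expect_equal(unname(fit$params$H), unname(or$H), tolerance = 1e-8)
  # implementation adds a 1e-10 ridge to Q and floors R at 1e-10
  expect_equal(unname(fit$params$Q), unname(or$Q), tolerance = 1e-8)
  expect_equal(unname(diag(fit$params$R)), unname(pmax(or$R_diag, 1e-10)),
               tolerance = 1e-8)
  expect_equal(unname(fit$params$mu0), unname(or$mu0), tolerance = 1e-8)
})

test_that("EM reaches at least the generating parameters' likelihood on long data", {
  p <- rand_params(2, 10, seed = 61)
  sim <- simulate_ssm(p, T = 200, seed = 1)
  fit <- em_fit(sim$data, m = 2, max_iter = 300, tol = 1e-9)
  truth_ll <- kalman_filter_smoother(p, fit$centered_data)$loglik
  expect_gte(fit$loglik, truth_ll - 1e-3)
})

test_that("EM is bit-identical for identical data and config", {
  p <- rand_params(2, 4, seed = 71)
  sim <- simulate_ssm(p, T = 20, seed = 72)
  f1 <- em_fit(sim$data, m = 2, max_iter = 25, seed = 3, n_restarts = 2)
  f2 <- em_fit(sim$data, m = 2, max_iter = 25, seed = 3, n_restarts = 2)
  expect_identical(f1$trace$logliks, f2$trace$logliks)
  expect_identical(f1$params, f2$params)
})

test_that("EM rejects infeasible hidden dimensions and flags constant genes", {
  p <- rand_params(1, 3, seed = 81)
  sim <- simulate_ssm(p, T = 5, seed = 82)
  expect_error(em_fit(sim$data, m = 4), "min\\(l, T\\)")
  expect_error(em_fit(sim$data, m = 0), "min\\(l, T\\)")
  v <- sim$data$values
  v[2, ] <- 7  # constant expression row
  d <- expression_dataset(v, gene_ids = c("a", "b", "c"))
  expect_warning(em_fit(d, m = 1, max_iter = 5), "constant gene row")
})
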