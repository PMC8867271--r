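# Dense brute-force GP oracle: explicit inverse and determinant.
brute_gp <- function(X, y, theta) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- ard_rbf(X[i, ], X[j, ], theta)
  Ky <- K + theta$sigma_n^2 * diag(n)
  Kinv <- solve(Ky)
  lml <- -0.5 * drop(t(y) %*% Kinv %*% y) -
    0.5 * as.numeric(determinant(Ky)$modulus) - n / 2 * log(2 * pi)
  predict_at <- function(xs) {
    ks <- vapply(1:n, function(i) ard_rbf(xs, X[i, ], theta), numeric(1))
    kss <- ard_rbf(xs, xs, theta)
    list(mean = drop(ks %*% Kinv %*% y), variance = kss - drop(ks %*% Kinv %*% ks))
  }
  list(lml = lml, predict = predict_at)
}

test_that("ARD kernel evaluates its closed form and the irrelevance limit", {
  expect_equal(ard_rbf(0, 0, c(2, 1, 1)), 4)
  expect_equal(ard_rbf(0, 1, c(2, 1, 1)), 4 * exp(-0.5))
  th_long <- list(sigma_f = 1, sigma_n = 1, lengthscales = c(0.5, 1e9))
  expect_equal(ard_rbf(c(0.2, 0), c(0.2, 1), th_long),
               ard_rbf(c(0.2, 5), c(0.2, -5), th_long), tolerance = 1e-12)
  expect_error(ard_rbf(0, 1, c(-1, 1, 1)), "positive")
})

test_that("log marginal likelihood matches scalar closed form and dense oracle", {
  expect_equal(gp_log_marginal_likelihood(matrix(0, 1, 1), 1, c(1, 1, 1)),
               -0.25 - 0.5 * log(2) - 0.5 * log(2 * pi))
  # zero targets: only the complexity terms remain
  X0 <- matrix(seq(0, 1, length.out = 5))
  th <- list(sigma_f = 1.5, sigma_n = 0.3, lengthscales = 0.4)
  b0 <- brute_gp(X0, rep(0, 5), th)
  expect_equal(gp_log_marginal_likelihood(X0, rep(0, 5), th), b0$lml, tolerance = 1e-8)
  set.seed(3)
  for (trial in 1:4) {
    n <- sample(5:20, 1)
    d <- sample(1:3, 1)
    X <- matrix(runif(n * d), n, d)
    y <- rnorm(n)
    theta <- list(sigma_f = runif(1, 0.5, 2), sigma_n = runif(1, 0.05, 0.5),
                  lengthscales = runif(d, 0.2, 2))
    expect_equal(gp_log_marginal_likelihood(X, y, theta), brute_gp(X, y, theta)$lml,
                 tolerance = 1e-8)
  }
})

test_that("predictive distribution matches the dense oracle and scalar case", {
  # single observation at 0 with unit signal and noise: mean 1/2, var 1/2
  X <- matrix(0, 1, 1)
  fitlike <- structure(list(X = X, y = 1, y_mean = 0, y_sd = 1, sigma_f = 1,
                            sigma_n = 1, lengthscales = 1,
                            L = chol(matrix(2, 1, 1)),
                            alpha = matrix(0.5, 1, 1)), class = "ard_gp")
  p <- predict(fitlike, matrix(0, 1, 1))
  expect_equal(p$mean, 0.5)
  expect_equal(p$variance, 0.5)
  set.seed(8)
  n <- 15; d <- 2
  Xr <- matrix(runif(n * d), n, d)
  yr <- rnorm(n)
  theta <- list(sigma_f = 1.2, sigma_n = 0.25, lengthscales = c(0.3, 0.8))
  oracle <- brute_gp(Xr, yr, theta)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- ard_rbf(Xr[i, ], Xr[j, ], theta)
  L <- chol(K + theta$sigma_n^2 * diag(n))
  gp <- structure(list(X = Xr, y = yr, y_mean = 0, y_sd = 1,
                       sigma_f = theta$sigma_f, sigma_n = theta$sigma_n,
                       lengthscales = theta$lengthscales, L = L,
                       alpha = backsolve(L, forwardsolve(t(L), yr))),
                  class = "ard_gp")
  xs <- matrix(runif(10 * d), 10, d)
  pr <- predict(gp, xs)
  for (i in 1:10) {
    ob <- oracle$predict(xs[i, ])
    expect_equal(pr$mean[i], ob$mean, tolerance = 1e-8)
    expect_equal(pr$variance[i], ob$variance, tolerance = 1e-8)
  }
  # prior recovery far away; variance bounded by signal variance
  far <- predict(gp, matrix(50, 1, d))
  expect_lt(abs(far$mean), 1e-6)
  expect_equal(far$variance, theta$sigma_f^2, tolerance = 1e-6)
  expect_true(all(pr$variance <= theta$sigma_f^2 + 1e-10))
})

test_that("analytic likelihood gradient matches central finite differences", {
  set.seed(4)
  X <- matrix(runif(24), 12, 2)
  y <- sin(3 * X[, 1]) + rnorm(12, 0, 0.1)
  D2 <- lapply(1:2, function(i) outer(X[, i], X[, i], "-")^2)
  nll <- isruq:::.gp_nll
  p <- c(log(1.1), log(0.2), log(0.5), log(1.3))
  g <- nll(p, D2, y, grad = TRUE)$gradient
  h <- 1e-5
  for (j in seq_along(p)) {
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    fd <- (nll(pp, D2, y, grad = FALSE)$value - nll(pm, D2, y, grad = FALSE)$value) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-5)
  }
})

test_that("fitting recovers interpolation, noise level and 1D functions", {
  # noise-free linear function: near-interpolation at training points
  X <- matrix(seq(0, 1, length.out = 12))
  y <- 2 * X[, 1] - 1
  fit <- gp_fit(X, y, restarts = 4, seed = 1)
  expect_lt(max(abs(predict(fit, X)$mean - y)), 1e-4)
  # pure-noise targets: fitted noise within a factor ~2 of the truth, most seeds
  s_true <- 0.7
  hits <- 0
  for (trial in 1:10) {
    yn <- with(list(), { set.seed(300 + trial); rnorm(64, 0, s_true) })
    Xn <- matrix(seq(0, 1, length.out = 64))
    fitn <- gp_fit(Xn, yn, restarts = 3, seed = trial)
    sn_orig <- fitn$sigma_n * fitn$y_sd # back to original scale
    if (sn_orig > s_true / 2 && sn_orig < s_true * 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # 1D recovery of sin(2 pi x)
  Xg <- matrix(seq(0, 1, length.out = 40))
  fitg <- gp_fit(Xg, sin(2 * pi * Xg[, 1]), restarts = 5, seed = 2)
  grid <- matrix(seq(0, 1, length.out = 200))
  expect_lt(max(abs(predict(fitg, grid)$mean - sin(2 * pi * grid[, 1]))), 1e-2)
})

test_that("more restarts never lowers the best likelihood; fits are seeded", {
  set.seed(9)
  X <- matrix(runif(30), 15, 2)
  y <- X[, 1]^2 + rnorm(15, 0, 0.05)
  f2 <- gp_fit(X, y, restarts = 2, seed = 5)
  f6 <- gp_fit(X, y, restarts = 6, seed = 5)
  expect_gte(f6$log_marginal, f2$log_marginal - 1e-9)
  expect_identical(coef(gp_fit(X, y, restarts = 3, seed = 7)),
                   coef(gp_fit(X, y, restarts = 3, seed = 7)))
})
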