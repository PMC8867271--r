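# Single-output Gaussian-process regression with an ARD squared-exponential
# kernel plus independent Gaussian noise.
#
# Hyperparameters theta = (sigma_f, sigma_n, l_1..l_d) are fitted by
# maximising the log marginal likelihood with L-BFGS-B in log-space
# (analytic gradients), from several seeded restarts.  Inputs are expected
# on the unit cube; targets are standardised internally and predictions
# un-standardised, so the zero-mean prior applies to the standardised scale.

#' ARD squared-exponential kernel
#'
#' `k(x, x') = sigma_f^2 * exp(-0.5 * sum_i (x_i - x'_i)^2 / l_i^2)`.
#' A separate lengthscale per input dimension performs automatic relevance
#' determination: an irrelevant coordinate is assigned a long lengthscale
#' and drops out of the covariance.
#'
#' @param x,x_prime input vectors of equal length d.
#' @param theta list or vector with `sigma_f`, `sigma_n` (unused here) and
#'   `lengthscales` (length d); all strictly positive.
#' @return the kernel value.
#' @export
#' @examples
#' ard_rbf(0, 1, list(sigma_f = 2, sigma_n = 1, lengthscales = 1)) # 4*exp(-0.5)
ard_rbf <- function(x, x_prime, theta) {
  th <- .gp_theta(theta, length(x))
  check_that(length(x_prime) == length(x), "x and x_prime must have equal length")
  th$sigma_f^2 * exp(-0.5 * sum((x - x_prime)^2 / th$lengthscales^2))
}

.gp_theta <- function(theta, d) {
  if (!is.list(theta)) {
    check_that(length(theta) == d + 2L, "theta must have %d entries (sigma_f, sigma_n, %d lengthscales)",
               d + 2L, d)
    theta <- list(sigma_f = theta[1L], sigma_n = theta[2L], lengthscales = theta[-(1:2)])
  }
  if (length(theta$lengthscales) == 1L && d > 1L) {
    theta$lengthscales <- rep(theta$lengthscales, d)
  }
  check_that(theta$sigma_f > 0 && theta$sigma_n > 0 && all(theta$lengthscales > 0),
             "GP hyperparameters must be strictly positive")
  check_that(length(theta$lengthscales) == d, "expected %d lengthscales, got %d",
             d, length(theta$lengthscales))
  theta
}

# kernel matrix between rows of X1 and X2 given lengthscale-scaled distances
.gp_kernmat <- function(X1, X2, sigma_f, lengthscales) {
  X1s <- sweep(X1, 2L, lengthscales, "/")
  X2s <- sweep(X2, 2L, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  sigma_f^2 * exp(-0.5 * pmax(d2, 0))
}

# Cholesky of K + sigma_n^2 I with escalating jitter (1e-10 -> 1e-6)
.gp_chol <- function(K, sigma_n2) {
  n <- nrow(K)
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(K + diag(sigma_n2 + jit, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
  }
  stop("covariance factorization failed even after jitter escalation up to 1e-6", call. = FALSE)
}

#' Log marginal likelihood of a GP with ARD-RBF kernel
#'
#' `-0.5 y' (K + sigma_n^2 I)^{-1} y - 0.5 log|K + sigma_n^2 I|
#' - (n/2) log(2 pi)`, evaluated via a Cholesky factorisation.
#'
#' @param X `n x d` input matrix.
#' @param y numeric response vector of length n.
#' @param theta hyperparameters as in [ard_rbf()].
#' @return the log marginal likelihood (scalar).
#' @export
gp_log_marginal_likelihood <- function(X, y, theta) {
  X <- as.matrix(X)
  n <- nrow(X)
  check_that(n >= 1L && length(y) == n, "X and y sizes disagree")
  th <- .gp_theta(theta, ncol(X))
  K <- .gp_kernmat(X, X, th$sigma_f, th$lengthscales)
  ch <- .gp_chol(K, th$sigma_n^2)
  a <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  -0.5 * sum(y * a) - sum(log(diag(ch$L))) - 0.5 * n * log(2 * pi)
}

# negative log marginal likelihood and gradient in log-hyperparameter space;
# p = (log sigma_f, log sigma_n, log l_1..l_d); D2 = list of per-dimension
# squared-difference matrices (cached across evaluations)
.gp_nll <- function(p, D2, y, grad = TRUE) {
  n <- length(y)
  d <- length(D2)
  sf2 <- exp(2 * p[1L]); sn2 <- exp(2 * p[2L])
  ell2 <- exp(2 * p[-(1:2)])
  M <- 0
  for (i in seq_len(d)) M <- M + D2[[i]] / ell2[i]
  K <- sf2 * exp(-0.5 * M)
  ch <- tryCatch(.gp_chol(K, sn2), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, d + 2L)))
  L <- ch$L
  a <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!grad) return(list(value = nll))
  Kinv <- chol2inv(L)
  W <- tcrossprod(a) - Kinv # d(loglik)/dK = 0.5 * W
  g <- numeric(d + 2L)
  g[1L] <- -0.5 * sum(W * (2 * K))            # d/d log sigma_f
  g[2L] <- -0.5 * 2 * sn2 * sum(diag(W))      # d/d log sigma_n
  for (i in seq_len(d)) {
    g[i + 2L] <- -0.5 * sum(W * (K * D2[[i]] / ell2[i]))
  }
  list(value = nll, gradient = g)
}

#' Fit a Gaussian process by marginal-likelihood maximisation
#'
#' Multi-start L-BFGS-B over log-hyperparameters.  Targets are standardised
#' to zero mean and unit variance before fitting (the zero-mean prior acts
#' on that scale); the noise SD is floored at `1e-5` (variance `1e-10`) so
#' interpolation of noise-free data stays numerically stable.
#'
#' @param X `n x d` input matrix, unit-cube scaled.
#' @param y numeric response vector (n >= 2).
#' @param restarts number of optimiser starts with seeded log-uniform
#'   initial lengthscales in `[1e-2, 1e1]`.
#' @param seed integer seed making the restarts reproducible.
#' @return an object of class `ard_gp` with fitted hyperparameters (original
#'   target scale), cached Cholesky factorisation and training data.
#' @export
gp_fit <- function(X, y, restarts = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  check_that(n >= 2L && length(y) == n, "need n >= 2 matching observations")
  check_that(all(is.finite(X)) && all(is.finite(y)), "non-finite training data")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1 # constant target: fit residual zeros
  ys <- (y - y_mean) / y_sd
  D2 <- lapply(seq_len(d), function(i) outer(X[, i], X[, i], "-")^2)
  lower <- c(log(1e-4), 0.5 * log(1e-10), rep(log(1e-3), d))
  upper <- c(log(1e3), log(10), rep(log(1e3), d))
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(r) {
      c(log(stats::runif(1L, 0.5, 2)),
        log(10^stats::runif(1L, -4, -0.5)),
        log(10^stats::runif(d, -2, 1)))
    })
  })
  best <- NULL
  fails <- character(0)
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0,
                   fn = function(p) .gp_nll(p, D2, ys, grad = FALSE)$value,
                   gr = function(p) .gp_nll(p, D2, ys, grad = TRUE)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit)); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all GP optimisation restarts failed: ", paste(unique(fails), collapse = "; "),
         call. = FALSE)
  }
  p <- best$par
  sigma_f <- exp(p[1L]); sigma_n <- max(exp(p[2L]), 1e-5)
  lengthscales <- exp(p[-(1:2)])
  K <- .gp_kernmat(X, X, sigma_f, lengthscales)
  ch <- .gp_chol(K, sigma_n^2)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), ys))
  structure(list(X = X, y = y, y_mean = y_mean, y_sd = y_sd,
                 sigma_f = sigma_f, sigma_n = sigma_n, lengthscales = lengthscales,
                 L = ch$L, alpha = alpha, jitter = ch$jitter,
                 log_marginal = -best$value, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "ard_gp")
}

#' @export
print.ard_gp <- function(x, ...) {
  cat(sprintf("ARD-RBF Gaussian process: n = %d, d = %d\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  sigma_f = %.4g, sigma_n = %.4g (standardised target scale)\n",
              x$sigma_f, x$sigma_n))
  cat("  lengthscales:", paste(sprintf("%.3g", x$lengthscales), collapse = ", "), "\n")
  cat(sprintf("  log marginal likelihood: %.4f\n", x$log_marginal))
  invisible(x)
}

#' @export
coef.ard_gp <- function(object, ...) {
  c(sigma_f = object$sigma_f, sigma_n = object$sigma_n,
    stats::setNames(object$lengthscales, paste0("l", seq_along(object$lengthscales))))
}

#' @export
logLik.ard_gp <- function(object, ...) {
  structure(object$log_marginal, df = length(object$lengthscales) + 2L, class = "logLik")
}

#' Predictive mean and variance of a fitted GP
#'
#' Conditional (posterior) distribution at new inputs: mean
#' `k(x*, X) (K + sigma_n^2 I)^{-1} y` and variance
#' `k(x*, x*) - k(x*, X)(K + sigma_n^2 I)^{-1} k(X, x*)`, mapped back to the
#' original target scale.
#'
#' @param object an `ard_gp` from [gp_fit()].
#' @param newdata `m x d` matrix of prediction inputs.
#' @param ... unused.
#' @return list with components `mean` and `variance` (length m).
#' @export
predict.ard_gp <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (ncol(Xs) != ncol(object$X) && nrow(Xs) == ncol(object$X)) Xs <- t(Xs)
  check_that(ncol(Xs) == ncol(object$X), "newdata must have %d columns", ncol(object$X))
  Ks <- .gp_kernmat(Xs, object$X, object$sigma_f, object$lengthscales) # m x n
  mu <- drop(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks)) # n x m
  var_s <- pmax(object$sigma_f^2 - colSums(v^2), 0)
  list(mean = object$y_mean + object$y_sd * mu,
       variance = object$y_sd^2 * var_s)
}
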