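# Brute-force double-loop conditional-variance oracle for first-order
# indices: S_i = Var_{x_i}(E[f | x_i]) / Var(f).  Sized so that its own
# Monte Carlo noise is well below the comparison tolerance.
brute_first_order <- function(f, d, n_outer = 512, n_inner = 2048, seed = 1) {
  set.seed(seed)
  total_var <- var(f(matrix(runif(65536 * d), ncol = d)))
  vapply(seq_len(d), function(i) {
    # stratified outer grid: removes outer-loop sampling noise; the smooth
    # conditional mean is integrated by midpoint quadrature
    cond_means <- vapply(seq_len(n_outer), function(o) {
      X <- matrix(runif(n_inner * d), ncol = d)
      X[, i] <- (o - 0.5) / n_outer
      mean(f(X))
    }, numeric(1))
    var(cond_means) / total_var
  }, numeric(1))
}

unit_space <- function(d) parameter_space(paste0("x", 1:d), rep(0, d), rep(1, d))

test_that("Saltelli design has the documented structure", {
  sp <- isr_parameter_space()
  des <- saltelli_matrices(sp, 64, seed = 2)
  expect_equal(dim(des$A), c(64, 4))
  expect_equal(length(des$AB), 4)
  for (i in 1:4) {
    expect_identical(des$AB[[i]][, i], des$B[, i])
    expect_identical(des$AB[[i]][, -i], des$A[, -i])
  }
  inbox <- function(M) all(sweep(M, 2, sp$mins, ">=") & sweep(M, 2, sp$maxs, "<="))
  expect_true(inbox(des$A) && inbox(des$B))
  expect_identical(saltelli_matrices(sp, 64, seed = 2)$A, des$A)
  expect_error(saltelli_matrices(sp, 1), ">= 2")
})

test_that("single-variable and additive functions give analytic indices", {
  sp <- unit_space(4)
  s1 <- sobol_indices(function(X) X[, 1], sp, 4096, seed = 1)
  expect_equal(s1$first[1], 1, tolerance = 0.02)
  expect_lt(max(abs(s1$first[2:4])), 0.02)
  # f = x1 + 2 x2: variance shares 1/5 and 4/5
  s2 <- sobol_indices(function(X) X[, 1] + 2 * X[, 2], sp, 4096, seed = 3)
  expect_equal(s2$first[1], 0.2, tolerance = 0.02)
  expect_equal(s2$first[2], 0.8, tolerance = 0.02)
  # additive: totals match first order
  expect_equal(s2$total, s2$first, tolerance = 0.02)
})

test_that("Ishigami indices match the analytic decomposition", {
  a <- 7; b <- 0.1
  sp <- parameter_space(paste0("x", 1:3), rep(-pi, 3), rep(pi, 3))
  ish <- function(X) sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  s <- sobol_indices(ish, sp, 2^14, seed = 4)
  expect_equal(s$first[1], 0.3139, tolerance = 0.02)
  expect_equal(s$first[2], 0.4424, tolerance = 0.02)
  expect_equal(s$first[3], 0, tolerance = 0.02)
  expect_equal(s$total[1], 0.5576, tolerance = 0.02)
  expect_equal(s$total[3], 0.2437, tolerance = 0.02)
  expect_true(all(s$total >= s$first - 0.01))
})

test_that("estimators agree with the double-loop conditional-variance oracle", {
  f <- function(X) X[, 1]^2 + 0.5 * X[, 2] * X[, 3] + 0.3 * X[, 3]
  sp <- unit_space(3)
  s <- sobol_indices(f, sp, 2^13, seed = 6)
  oracle <- brute_first_order(f, 3, seed = 7)
  expect_lt(max(abs(s$first - oracle)), 0.02)
})

test_that("multi-output estimation matches column-wise scalar estimation", {
  sp <- unit_space(3)
  fv <- function(X) cbind(X[, 1], X[, 1] + 2 * X[, 2])
  des <- saltelli_matrices(sp, 2048, seed = 8)
  fA <- fv(des$A); fB <- fv(des$B); fAB <- lapply(des$AB, fv)
  Sm <- first_order_indices(fA, fB, fAB)
  expect_equal(dim(Sm), c(3, 2))
  S1 <- first_order_indices(fA[, 1], fB[, 1], lapply(fAB, function(m) m[, 1]))
  expect_equal(Sm[, 1], S1)
  Tm <- total_order_indices(fA, fB, fAB)
  expect_true(all(Tm >= Sm - 0.01))
})

test_that("zero-variance output is rejected", {
  sp <- unit_space(2)
  expect_error(sobol_indices(function(X) rep(1, nrow(X)), sp, 64, seed = 1),
               "variance is zero")
})
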