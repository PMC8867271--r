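# Variance-based global sensitivity analysis.
#
# Saltelli's paired-matrix design: base matrices A and B from complementary
# halves of a scrambled Sobol design in 2d dimensions, plus the d hybrids
# AB_i (A with column i replaced from B), for (d+2)N model evaluations.
# First-order indices use the Saltelli-2010 estimator
# S_i = mean(fB * (fAB_i - fA)) / Var(f); total indices use Jansen's
# S_Ti = mean((fA - fAB_i)^2) / (2 Var(f)).  Negative estimates are
# reported as-is; the variance normaliser comes from the pooled (fA, fB)
# sample.

#' Saltelli sampling design for Sobol index estimation
#'
#' @param space a `param_space` of dimension d.
#' @param N base sample size (>= 2; powers of 2 recommended for the Sobol
#'   sequence).
#' @param seed scramble seed for the underlying Sobol design.
#' @return a `saltelli_design`: list with matrices `A`, `B` (`N x d`) and
#'   `AB` (list of d matrices, `AB[[i]]` = A with column i from B).
#' @export
saltelli_matrices <- function(space, N, seed = 1L) {
  stopifnot(inherits(space, "param_space"))
  check_that(N >= 2, "N must be >= 2, got %s", format(N))
  d <- space$d
  U <- sobol_sequence(N, 2L * d, scramble_seed = seed)
  A <- scale_unit_to_physical(U[, seq_len(d), drop = FALSE], space)
  B <- scale_unit_to_physical(U[, d + seq_len(d), drop = FALSE], space)
  AB <- lapply(seq_len(d), function(i) { M <- A; M[, i] <- B[, i]; M })
  structure(list(A = A, B = B, AB = AB, N = as.integer(N), d = d,
                 seed = as.integer(seed)),
            class = "saltelli_design")
}

# core estimators; fA, fB: N x q matrices (q output dimensions), fAB: list of
# d N x q matrices. Returns list(first = d x q, total = d x q, variance = q).
.sobol_estimate <- function(fA, fB, fAB) {
  fA <- as.matrix(fA); fB <- as.matrix(fB)
  d <- length(fAB)
  q <- ncol(fA)
  V <- apply(rbind(fA, fB), 2L, stats::var)
  check_that(any(V > 0), "total variance is zero; Sobol indices undefined")
  Vsafe <- ifelse(V > 0, V, NA_real_) # degenerate days (e.g. day 0) -> NA
  S <- matrix(NA_real_, d, q)
  ST <- matrix(NA_real_, d, q)
  for (i in seq_len(d)) {
    fABi <- as.matrix(fAB[[i]])
    S[i, ] <- colMeans(fB * (fABi - fA)) / Vsafe
    ST[i, ] <- colMeans((fA - fABi)^2) / (2 * Vsafe)
  }
  list(first = S, total = ST, variance = V)
}

#' First-order Sobol indices from design evaluations
#'
#' @param fA,fB model outputs on the base matrices (length-N vectors or
#'   `N x q` matrices for q output dimensions).
#' @param fAB outputs on the hybrid matrices: a list of d vectors/matrices.
#' @return `d x q` matrix (dropped to a vector for scalar output) of
#'   first-order indices.
#' @export
first_order_indices <- function(fA, fB, fAB) {
  est <- .sobol_estimate(fA, fB, fAB)
  if (ncol(as.matrix(fA)) == 1L) drop(est$first) else est$first
}

#' @rdname first_order_indices
#' @return `total_order_indices`: total-effect indices of the same shape.
#' @export
total_order_indices <- function(fA, fB, fAB) {
  est <- .sobol_estimate(fA, fB, fAB)
  if (ncol(as.matrix(fA)) == 1L) drop(est$total) else est$total
}

#' Sobol indices of an arbitrary function over a parameter space
#'
#' Convenience wrapper: builds the Saltelli design, evaluates `f` row-wise
#' and returns both index families.  Used for analytic benchmarks (additive
#' functions, Ishigami).
#'
#' @param f function taking a parameter matrix (`n x d`) and returning a
#'   vector (or `n x q` matrix) of outputs.
#' @inheritParams saltelli_matrices
#' @return list with `first`, `total` (and the design size `N`).
#' @export
sobol_indices <- function(f, space, N, seed = 1L) {
  des <- saltelli_matrices(space, N, seed)
  fA <- f(des$A); fB <- f(des$B)
  fAB <- lapply(des$AB, f)
  est <- .sobol_estimate(fA, fB, fAB)
  scal <- ncol(as.matrix(fA)) == 1L
  list(first = if (scal) drop(est$first) else est$first,
       total = if (scal) drop(est$total) else est$total,
       N = des$N)
}

#' Time-resolved Sobol sensitivity of a fitted surrogate
#'
#' Per-day first-order and total indices of a QoI predicted by a
#' [pod_gp()] surrogate, with confidence intervals from replicated
#' scrambles of the Saltelli design.
#'
#' @param model a fitted `pod_gp`.
#' @param space parameter space (defaults to the model's training space).
#' @param N base Saltelli sample size per replicate.
#' @param reps number of independently scrambled replicates.
#' @param master_seed master seed; replicate r uses scramble seed
#'   `derive_seed(master_seed, r)`.
#' @param qoi which QoI to analyse (`"acsa"` or `"mral"`).
#' @return a `sobol_result`: arrays `first` and `total` (`d x Nt`, mean over
#'   replicates), `ci_first` / `ci_total` (2.5/97.5 across-replicate
#'   percentiles, `2 x d x Nt`), and bookkeeping fields.
#' @export
sensitivity_over_time <- function(model, space = model$space, N = 4096L,
                                  reps = 10L, master_seed = 1L, qoi = "acsa") {
  stopifnot(inherits(model, "pod_gp"))
  check_that(qoi %in% names(model$qois), "QoI '%s' not in the fitted model", qoi)
  d <- space$d
  S_reps <- NULL
  ST_reps <- NULL
  for (r in seq_len(reps)) {
    des <- saltelli_matrices(space, N, seed = derive_seed(master_seed, r))
    # one batched surrogate evaluation over the whole design
    stacked <- rbind(des$A, des$B, do.call(rbind, des$AB))
    pred <- predict(model, stacked, qois = qoi)[[qoi]]$mean
    fA <- pred[seq_len(N), , drop = FALSE]
    fB <- pred[N + seq_len(N), , drop = FALSE]
    fAB <- lapply(seq_len(d), function(i)
      pred[2L * N + (i - 1L) * N + seq_len(N), , drop = FALSE])
    est <- .sobol_estimate(fA, fB, fAB)
    if (is.null(S_reps)) {
      nt <- ncol(est$first)
      S_reps <- array(NA_real_, c(reps, d, nt))
      ST_reps <- array(NA_real_, c(reps, d, nt))
    }
    S_reps[r, , ] <- est$first
    ST_reps[r, , ] <- est$total
  }
  ci <- function(a) apply(a, c(2L, 3L), stats::quantile, probs = c(0.025, 0.975),
                          na.rm = TRUE)
  structure(list(first = apply(S_reps, c(2L, 3L), mean),
                 total = apply(ST_reps, c(2L, 3L), mean),
                 ci_first = ci(S_reps), ci_total = ci(ST_reps),
                 replicates_first = S_reps, replicates_total = ST_reps,
                 parameters = space$names, days = 0:(dim(S_reps)[3L] - 1L),
                 N = as.integer(N), reps = as.integer(reps),
                 master_seed = as.integer(master_seed), qoi = qoi),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol sensitivity of %s over time (N = %d, %d replicates)\n",
              toupper(x$qoi), x$N, x$reps))
  sel <- x$days %in% c(2, 5, 10, 15, 20, 30)
  tab <- round(x$first[, sel, drop = FALSE], 3)
  dimnames(tab) <- list(x$parameters, paste0("day_", x$days[sel]))
  cat("First-order indices:\n")
  print(tab)
  cat(sprintf("Sum of first-order indices at day %d: %.3f\n",
              max(x$days), sum(x$first[, ncol(x$first)])))
  invisible(x)
}

#' @export
plot.sobol_result <- function(x, which = c("first", "total"), ...) {
  which <- match.arg(which)
  M <- x[[which]]
  graphics::matplot(x$days, t(M), type = "l", lty = 1, lwd = 2,
                    xlab = "day", ylab = sprintf("%s-order Sobol index", which),
                    main = sprintf("%s sensitivity (%s)", toupper(x$qoi), which), ...)
  graphics::legend("topright", legend = x$parameters, col = seq_len(nrow(M)),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
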