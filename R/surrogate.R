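# POD + GP surrogate of the time-dependent restenosis response.
#
# Training: choose snapshots, SVD + energy-based rank selection per QoI,
# project every training response onto the retained modes, and fit one
# single-output ARD GP per projection coefficient.  Prediction: per-GP
# coefficient means reconstructed through the basis; predictive variance
# propagated under coefficient independence, Var(y_t) = sum_j Var(a_j)
# phi_jt^2.

#' Fit a POD + Gaussian-process surrogate
#'
#' The central fitting function of the package: reduces each quantity of
#' interest (QoI) time series to a few POD coefficients and learns each
#' coefficient as an independent single-output GP over the uncertain inputs.
#'
#' @param dataset an `isr_dataset` from [generate_dataset()], or any list
#'   with `samples` (`n x d`), a matrix per QoI named in `qois`, and a
#'   `space` (`param_space`).
#' @param qois character vector of QoI names to fit (default both `"acsa"`
#'   and `"mral"`).
#' @param n_snapshots number of snapshot responses used for the SVD.
#' @param energy relative-energy threshold for rank truncation.
#' @param restarts optimiser restarts per coefficient GP.
#' @param seed master seed (snapshot selection, GP restarts).
#' @return an object of class `pod_gp` with per-QoI `basis` and coefficient
#'   GP lists; methods: [predict.pod_gp()], `print`, `summary`, `coef`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(n = 64, seed = 1)
#' fit <- pod_gp(ds, n_snapshots = 32, restarts = 2, seed = 1)
#' pred <- predict(fit, ds$samples[1:2, ])
#' }
pod_gp <- function(dataset, qois = c("acsa", "mral"), n_snapshots = 100L,
                   energy = 0.999, restarts = 10L, seed = 1L) {
  check_that(!is.null(dataset$samples), "dataset must carry a samples matrix")
  X <- as.matrix(dataset$samples)
  n <- nrow(X)
  check_that(n >= n_snapshots, "dataset rows (%d) must be >= n_snapshots (%d)",
             n, as.integer(n_snapshots))
  space <- dataset$space
  check_that(inherits(space, "param_space"), "dataset must carry its param_space")
  U <- scale_physical_to_unit(X, space)
  if (!is.matrix(U)) U <- matrix(U, nrow = n)
  per_qoi <- list()
  for (q in qois) {
    Y <- as.matrix(dataset[[q]])
    check_that(nrow(Y) == n, "QoI '%s' row count disagrees with samples", q)
    snap_seed <- derive_seed(seed, match(q, qois))
    S <- build_snapshots(Y, n_snapshots, seed = snap_seed)
    basis <- select_rank(pod_decompose(S), energy)
    alpha <- pod_project(basis, t(Y)) # k x n
    if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = 1L)
    gps <- lapply(seq_len(basis$k), function(j) {
      gp_fit(U, alpha[j, ], restarts = restarts,
             seed = derive_seed(seed, 100L * match(q, qois) + j))
    })
    per_qoi[[q]] <- list(basis = basis, gps = gps, snapshot_seed = snap_seed)
  }
  structure(list(qois = per_qoi, space = space, n_train = n,
                 n_snapshots = as.integer(n_snapshots), energy = energy,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "pod_gp")
}

#' @export
print.pod_gp <- function(x, ...) {
  cat(sprintf("POD + GP surrogate: %d training runs, %d snapshots, energy threshold %g\n",
              x$n_train, x$n_snapshots, x$energy))
  for (q in names(x$qois)) {
    b <- x$qois[[q]]$basis
    cat(sprintf("  %s: rank k = %d (energy %.6f), %d coefficient GPs\n",
                q, b$k, relative_energy(b, b$k), length(x$qois[[q]]$gps)))
  }
  invisible(x)
}

#' @export
summary.pod_gp <- function(object, ...) {
  cat("POD + GP surrogate\n")
  print(object)
  for (q in names(object$qois)) {
    cat(sprintf("\n%s coefficient GPs (hyperparameters on standardised scale):\n", q))
    hp <- t(vapply(object$qois[[q]]$gps, coef, numeric(2L + object$space$d)))
    rownames(hp) <- paste0("alpha_", seq_len(nrow(hp)))
    print(round(hp, 4))
  }
  invisible(object)
}

#' @export
coef.pod_gp <- function(object, ...) {
  lapply(object$qois, function(e) t(vapply(e$gps, coef, numeric(2L + object$space$d))))
}

# enforce QoI series shape constraints: ACSA non-increasing in time, MRAL
# non-decreasing and within [0, 1).  Antitonic/isotonic projection via PAVA.
.clean_series <- function(y, qoi) {
  if (qoi == "acsa") {
    if (any(diff(y) > 0)) y <- -stats::isoreg(seq_along(y), -y)$yf
  } else if (qoi == "mral") {
    if (any(diff(y) < 0)) y <- stats::isoreg(seq_along(y), y)$yf
    y <- pmin(pmax(y, 0), 1 - 1e-12)
  }
  y
}

#' Predict QoI time series at new parameter vectors
#'
#' Coefficient means from each GP, reconstructed through the POD basis.
#' Predictions violating the physical shape constraints (ACSA non-increasing,
#' MRAL non-decreasing in `[0,1)`) are repaired by an isotonic projection;
#' the raw reconstruction is returned alongside.  Inputs outside the training
#' box trigger an extrapolation warning, not an error.
#'
#' @param object a fitted `pod_gp`.
#' @param newdata `m x d` matrix of parameter vectors in physical units (or
#'   a single vector).
#' @param qois which QoIs to predict (default: all fitted).
#' @param raw if `TRUE`, skip the isotonic repair.
#' @param ... unused.
#' @return named list per QoI: `mean` (`m x Nt`), `raw` (`m x Nt`,
#'   unconstrained reconstruction) and `variance` (`m x Nt`, elementwise
#'   reconstruction variance under coefficient independence).
#' @export
predict.pod_gp <- function(object, newdata, qois = names(object$qois), raw = FALSE, ...) {
  Xs <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  check_that(ncol(Xs) == object$space$d, "newdata must have %d columns", object$space$d)
  out_of_box <- any(sweep(Xs, 2L, object$space$mins, "<") |
                    sweep(Xs, 2L, object$space$maxs, ">"))
  if (out_of_box) warning("some inputs lie outside the training box; extrapolating")
  Us <- scale_physical_to_unit(Xs, object$space)
  if (!is.matrix(Us)) Us <- matrix(Us, nrow = nrow(Xs))
  out <- list()
  for (q in qois) {
    e <- object$qois[[q]]
    k <- e$basis$k
    phi <- e$basis$phi[, seq_len(k), drop = FALSE] # Nt x k
    m <- nrow(Us)
    amean <- matrix(NA_real_, k, m)
    avar <- matrix(NA_real_, k, m)
    for (j in seq_len(k)) {
      pr <- predict(e$gps[[j]], Us)
      amean[j, ] <- pr$mean
      avar[j, ] <- pr$variance
    }
    ymean <- t(phi %*% amean)       # m x Nt
    yvar <- t(phi^2 %*% avar)       # independence approximation
    cleaned <- if (raw) ymean else t(apply(ymean, 1L, .clean_series, qoi = q))
    out[[q]] <- list(mean = cleaned, raw = ymean, variance = yvar)
  }
  out
}

#' Fourfold (or k-fold) cross-validation of the surrogate
#'
#' Random fold assignment (seeded); within each fold the POD basis and every
#' coefficient GP are retrained on the remaining folds (strict held-out
#' protocol) and the held-out responses are scored with the mean relative L2
#' errors of the projection alone (`e_POD`) and of the full surrogate
#' (`e_GP`).
#'
#' @param dataset an `isr_dataset`.
#' @param folds number of folds (default 4).
#' @param repetitions independent repetitions with fresh fold assignments.
#' @param seed master seed.
#' @param qois QoIs to score.
#' @inheritParams pod_gp
#' @return a `cv_report`: per QoI, mean `e_POD` / `e_GP` over folds and
#'   repetitions plus per-fold values and raw (unaveraged) error sums.
#' @export
cross_validate <- function(dataset, folds = 4L, repetitions = 1L, seed = 1L,
                           qois = c("acsa", "mral"), n_snapshots = 100L,
                           energy = 0.999, restarts = 10L) {
  X <- as.matrix(dataset$samples)
  n <- nrow(X)
  check_that(n >= folds, "need at least as many rows as folds")
  res <- list()
  for (q in qois) res[[q]] <- list(e_pod = c(), e_gp = c(), rep = c(), fold = c(), sum_pod = c(), sum_gp = c())
  for (r in seq_len(repetitions)) {
    assign_seed <- derive_seed(seed, 7000L + r)
    fold_id <- with_seed(assign_seed, sample(rep_len(seq_len(folds), n)))
    for (f in seq_len(folds)) {
      test_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      check_that(length(test_idx) >= 2L, "fold %d has fewer than 2 samples", f)
      sub <- list(samples = X[train_idx, , drop = FALSE], space = dataset$space)
      for (q in qois) sub[[q]] <- dataset[[q]][train_idx, , drop = FALSE]
      fit <- pod_gp(sub, qois = qois,
                    n_snapshots = min(n_snapshots, length(train_idx)),
                    energy = energy, restarts = restarts,
                    seed = derive_seed(seed, 8000L + r * folds + f))
      pred <- predict(fit, X[test_idx, , drop = FALSE], qois = qois, raw = TRUE)
      for (q in qois) {
        Ytest <- dataset[[q]][test_idx, , drop = FALSE]
        nrm <- sqrt(rowSums(Ytest^2))
        e_pod <- pod_relative_error(fit$qois[[q]]$basis, Ytest)
        rel_gp <- sqrt(rowSums((Ytest - pred[[q]]$raw)^2)) / nrm
        res[[q]]$e_pod <- c(res[[q]]$e_pod, as.numeric(e_pod))
        res[[q]]$e_gp <- c(res[[q]]$e_gp, mean(rel_gp))
        res[[q]]$sum_pod <- c(res[[q]]$sum_pod, attr(e_pod, "sum"))
        res[[q]]$sum_gp <- c(res[[q]]$sum_gp, sum(rel_gp))
        res[[q]]$rep <- c(res[[q]]$rep, r)
        res[[q]]$fold <- c(res[[q]]$fold, f)
      }
    }
  }
  out <- lapply(res, function(e) {
    list(e_pod = mean(e$e_pod), e_gp = mean(e$e_gp),
         per_fold = data.frame(rep = e$rep, fold = e$fold,
                               e_pod = e$e_pod, e_gp = e$e_gp,
                               sum_pod = e$sum_pod, sum_gp = e$sum_gp))
  })
  structure(list(qois = out, folds = as.integer(folds),
                 repetitions = as.integer(repetitions), seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Surrogate cross-validation: %d folds x %d repetition(s)\n",
              x$folds, x$repetitions))
  for (q in names(x$qois)) {
    cat(sprintf("  %s: e_POD = %.5f, e_GP = %.5f (mean relative L2 over held-out runs)\n",
                q, x$qois[[q]]$e_pod, x$qois[[q]]$e_gp))
  }
  invisible(x)
}
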