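# Proper orthogonal decomposition of the time-series response.
#
# A snapshot matrix S (days x snapshots) is decomposed by thin SVD; the
# leading k left singular vectors form an orthonormal basis whose truncation
# error is Eckart-Young optimal.  The rank is chosen as the smallest k whose
# relative energy (leading squared-singular-value mass) exceeds a threshold,
# 99.9% by default.  Snapshots are used raw, without mean-centering, so the
# energy ratio refers to the responses themselves.

#' Assemble a snapshot matrix from a dataset QoI matrix
#'
#' Selects `m` responses uniformly without replacement (reproducibly, from
#' `seed`) and stacks them as columns.
#'
#' @param qoi_matrix `n x Nt` matrix of responses (rows = runs).
#' @param m number of snapshots, `1 <= m <= n`.
#' @param seed integer seed for the random selection.
#' @return `Nt x m` snapshot matrix with attribute `snapshot_idx` (the rows
#'   selected).
#' @export
build_snapshots <- function(qoi_matrix, m, seed = 1L) {
  qoi_matrix <- as.matrix(qoi_matrix)
  n <- nrow(qoi_matrix)
  check_that(m >= 1 && m <= n, "need 1 <= m <= n (m = %d, n = %d)", as.integer(m), n)
  idx <- with_seed(seed, sample.int(n, m))
  S <- t(qoi_matrix[idx, , drop = FALSE])
  check_that(all(is.finite(S)), "snapshot matrix contains non-finite entries")
  attr(S, "snapshot_idx") <- idx
  S
}

#' Singular value decomposition of a snapshot matrix
#'
#' Thin SVD `S = U diag(sigma) V'`; all singular values are retained, and
#' truncation is deferred to [select_rank()] / the `k` argument of
#' [pod_project()].
#'
#' @param S `Nt x Ns` snapshot matrix.
#' @return an object of class `pod_basis`: orthonormal modes `phi`
#'   (`Nt x Ns`), `singular_values`, and the truncation rank `k`
#'   (initialised to `Ns`).
#' @export
pod_decompose <- function(S) {
  S <- as.matrix(S)
  check_that(all(is.finite(S)), "snapshot matrix contains non-finite entries")
  sv <- svd(S)
  structure(list(phi = sv$u, singular_values = sv$d, v = sv$v,
                 k = length(sv$d), n_snapshots = ncol(S),
                 snapshot_idx = attr(S, "snapshot_idx")),
            class = "pod_basis")
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("POD basis: %d modes from %d snapshots, truncation rank k = %d (energy %.5f)\n",
              length(x$singular_values), x$n_snapshots, x$k, relative_energy(x, x$k)))
  invisible(x)
}

#' Relative energy captured by the leading k modes
#'
#' `sum(sigma[1:k]^2) / sum(sigma^2)`, the fraction of squared Frobenius mass
#' of the snapshot matrix captured by a rank-k truncation.
#'
#' @param basis a `pod_basis`.
#' @param k truncation rank, `1 <= k <= Ns`.
#' @return the relative energy in `(0, 1]`.
#' @export
relative_energy <- function(basis, k) {
  sv2 <- basis$singular_values^2
  total <- sum(sv2)
  check_that(total > 0, "relative energy undefined: snapshot matrix is zero")
  check_that(k >= 1 && k <= length(sv2), "k out of range 1..%d", length(sv2))
  sum(sv2[seq_len(k)]) / total
}

#' Select the truncation rank by an energy threshold
#'
#' Smallest k whose [relative_energy()] reaches `threshold` (default 99.9%).
#'
#' @param basis a `pod_basis`.
#' @param threshold energy fraction in `(0, 1]`.
#' @return the basis with its `k` field set (invisibly also the rank as
#'   attribute-free integer via `$k`).
#' @export
select_rank <- function(basis, threshold = 0.999) {
  check_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  sv2 <- basis$singular_values^2
  en <- cumsum(sv2) / sum(sv2)
  basis$k <- which(en >= threshold - 1e-15)[1L]
  basis
}

#' Project responses onto the POD basis, and reconstruct from coefficients
#'
#' `pod_project` computes the coefficient vector(s) `alpha = Phi_k' y`;
#' `pod_reconstruct` maps coefficients back, `yhat = Phi_k alpha`.
#'
#' @param basis a `pod_basis` (its `k` field sets the truncation).
#' @param y response vector of length Nt, or an `Nt x m` matrix of columns.
#' @param k optional override of the truncation rank.
#' @return `pod_project`: `k x m` coefficient matrix (or length-k vector);
#'   `pod_reconstruct`: responses of the original shape.
#' @export
pod_project <- function(basis, y, k = basis$k) {
  phi <- basis$phi[, seq_len(k), drop = FALSE]
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  check_that(nrow(ym) == nrow(phi), "response length %d does not match basis rows %d",
             nrow(ym), nrow(phi))
  a <- crossprod(phi, ym)
  if (!is.matrix(y)) a <- drop(a)
  a
}

#' @rdname pod_project
#' @param alpha coefficient vector (length k) or `k x m` matrix.
#' @export
pod_reconstruct <- function(basis, alpha, k = basis$k) {
  phi <- basis$phi[, seq_len(k), drop = FALSE]
  am <- if (is.matrix(alpha)) alpha else matrix(alpha, ncol = 1L)
  check_that(nrow(am) == k, "coefficient length %d does not match rank %d", nrow(am), k)
  yh <- phi %*% am
  if (!is.matrix(alpha)) yh <- drop(yh)
  yh
}

#' Mean relative L2 projection error over a validation set
#'
#' For each response y, the relative error `||y - Phi Phi' y|| / ||y||` of
#' its rank-k projection; returned as the mean over responses, with the raw
#' sum kept as an attribute.
#'
#' @param basis a `pod_basis`.
#' @param ys `m x Nt` matrix of validation responses (rows = responses).
#' @param k optional truncation override.
#' @return mean relative L2 error (attribute `sum` holds the unaveraged
#'   total).
#' @export
pod_relative_error <- function(basis, ys, k = basis$k) {
  ys <- as.matrix(ys)
  check_that(nrow(ys) >= 1L, "need at least one validation response")
  Y <- t(ys) # Nt x m
  nrm <- sqrt(colSums(Y^2))
  check_that(all(nrm > 0), "zero-norm response in validation set")
  resid <- Y - pod_reconstruct(basis, pod_project(basis, Y, k), k)
  rel <- sqrt(colSums(resid^2)) / nrm
  structure(mean(rel), sum = sum(rel), per_sample = rel)
}
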