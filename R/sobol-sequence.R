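# Sobol low-discrepancy sequence generator.
#
# Gray-code construction from Joe & Kuo direction numbers (dimensions up to
# 10, enough for a 4-parameter study plus its doubled Saltelli design), with
# optional Owen-type scrambling implemented as Matousek random linear
# scrambling (lower-triangular GF(2) matrix applied to the direction
# numbers) plus a random digital shift.  All integer work uses 31 bits so
# values stay within R's signed 32-bit integers.

.sobol_nbits <- 31L

# Primitive polynomial degree `s`, coefficient code `a` and initial direction
# integers m_1..m_s for dimensions 2..10 (dimension 1 is the van der Corput
# sequence in base 2).
.sobol_dirtab <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

.sobol_max_dim <- function() length(.sobol_dirtab) + 1L

# direction numbers as an nbits x d integer matrix, scaled by 2^31
.sobol_directions <- function(d) {
  nb <- .sobol_nbits
  V <- matrix(0L, nrow = nb, ncol = d)
  V[, 1L] <- as.integer(2^(nb - seq_len(nb))) # van der Corput
  if (d >= 2L) {
    for (j in 2:d) {
      rec <- .sobol_dirtab[[j - 1L]]
      s <- rec$s
      v <- integer(nb)
      v[seq_len(s)] <- as.integer(rec$m * 2^(nb - seq_len(s)))
      if (nb > s) {
        for (k in (s + 1L):nb) {
          vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
          if (s > 1L) {
            for (i in seq_len(s - 1L)) {
              if (bitwAnd(bitwShiftR(rec$a, s - 1L - i), 1L) == 1L) {
                vk <- bitwXor(vk, v[k - i])
              }
            }
          }
          v[k] <- vk
        }
      }
      V[, j] <- v
    }
  }
  V
}

# parity of the 32-bit integer vector x (vectorised popcount mod 2)
.parity32 <- function(x) {
  x <- bitwXor(x, bitwShiftR(x, 16L))
  x <- bitwXor(x, bitwShiftR(x, 8L))
  x <- bitwXor(x, bitwShiftR(x, 4L))
  x <- bitwXor(x, bitwShiftR(x, 2L))
  x <- bitwXor(x, bitwShiftR(x, 1L))
  bitwAnd(x, 1L)
}

# Matousek linear matrix scramble of one dimension's direction numbers.
# Rows of the random lower-triangular GF(2) matrix (unit diagonal) are stored
# as integers in the same fixed-point convention as the direction numbers
# (row r has its diagonal bit at 2^(nbits - r)).  Uses the current RNG state.
.lms_scramble <- function(v) {
  nb <- .sobol_nbits
  out <- numeric(length(v))
  for (r in seq_len(nb)) {
    row <- 2^(nb - r)
    if (r > 1L) {
      bits <- as.integer(stats::runif(r - 1L) < 0.5)
      row <- row + sum(bits * 2^(nb - seq_len(r - 1L)))
    }
    out <- out + as.numeric(.parity32(bitwAnd(as.integer(row), v))) * 2^(nb - r)
  }
  as.integer(out)
}

# random 31-bit digital shift (uses current RNG state)
.digital_shift <- function() {
  hi <- as.numeric(sample.int(32768L, 1L) - 1L) # 15 bits
  lo <- as.numeric(sample.int(65536L, 1L) - 1L) # 16 bits
  as.integer(hi * 65536 + lo)
}

#' Sobol low-discrepancy sequence in the unit hypercube
#'
#' Generates `n` points of the Sobol sequence in `[0, 1)^d` using Gray-code
#' ordering.  With `scramble_seed = NULL` the classical (deterministic)
#' sequence is returned and its degenerate all-zeros first point is skipped;
#' with an integer seed the sequence is randomised by Matousek linear matrix
#' scrambling plus a digital shift (an Owen-type scrambling), reproducibly.
#'
#' @param n number of points (>= 1).
#' @param d dimension, between 1 and 10.
#' @param scramble_seed `NULL` for the unscrambled sequence, or an integer
#'   seed controlling the scrambling.
#' @return an `n x d` numeric matrix of points in the open unit cube.
#' @export
#' @examples
#' sobol_sequence(8, 2)
#' sobol_sequence(8, 2, scramble_seed = 1)
sobol_sequence <- function(n, d, scramble_seed = NULL) {
  check_that(is.numeric(n) && length(n) == 1L && n >= 1, "n must be a positive count, got %s", format(n))
  n <- as.integer(n)
  check_that(d >= 1L && d <= .sobol_max_dim(),
             "dimension d = %d outside supported range 1..%d", as.integer(d), .sobol_max_dim())
  d <- as.integer(d)
  V <- .sobol_directions(d)
  shift <- rep(0L, d)
  scrambled <- !is.null(scramble_seed)
  if (scrambled) {
    with_seed(as.integer(scramble_seed), {
      for (j in seq_len(d)) {
        V[, j] <- .lms_scramble(V[, j])
        shift[j] <- .digital_shift()
      }
    })
  }
  skip <- if (scrambled) 0L else 1L
  idx <- seq.int(skip, n + skip - 1L)
  g <- bitwXor(idx, bitwShiftR(idx, 1L))
  X <- matrix(0L, nrow = n, ncol = d)
  for (k in seq_len(.sobol_nbits)) {
    sel <- bitwAnd(g, bitwShiftL(1L, k - 1L)) != 0L
    if (!any(sel)) next
    for (j in seq_len(d)) {
      X[sel, j] <- bitwXor(X[sel, j], V[k, j])
    }
  }
  if (scrambled) {
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shift[j])
    U <- (X + 0.5) / 2^.sobol_nbits
  } else {
    U <- X / 2^.sobol_nbits
  }
  attr(U, "sobol") <- list(scrambled = scrambled,
                           scramble_seed = if (scrambled) as.integer(scramble_seed) else NA_integer_,
                           skip = skip)
  U
}

#' L2 star discrepancy of a point set
#'
#' Warnock's closed form for the L2 star discrepancy, used as a computable
#' proxy for the star discrepancy when comparing low-discrepancy designs with
#' pseudo-random ones.
#'
#' @param u an `n x d` matrix of points in the unit cube.
#' @return the L2 star discrepancy (a nonnegative scalar).
#' @export
l2_star_discrepancy <- function(u) {
  u <- as.matrix(u)
  n <- nrow(u)
  d <- ncol(u)
  t1 <- 3^(-d)
  t2 <- mean(apply((1 - u^2) / 2, 1L, prod))
  # pairwise product of (1 - max(u_ik, u_jk)) over k
  acc <- matrix(1, n, n)
  for (k in seq_len(d)) {
    acc <- acc * (1 - outer(u[, k], u[, k], pmax))
  }
  t3 <- sum(acc) / n^2
  sqrt(t1 - 2 * t2 + t3)
}
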