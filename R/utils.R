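# Internal helpers: seed management and deterministic seed derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards so library calls never disturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting: one master integer reproduces every random
#' component of a study (designs, emulator runs, fold assignments, replicate
#' scrambles).  A Lehmer-style mixing map keeps all derived seeds in
#' `[1, 2^31 - 2]`, exact in double arithmetic.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0); distinct streams give
#'   effectively unrelated seeds.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
derive_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m) + 1
  s <- as.numeric(stream) %% m
  # two multiplicative mixing rounds; products stay below 2^53
  x <- (x * 48271) %% m
  x <- (x + s * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x + 1)
}

# stopifnot-style check with a formatted message
check_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
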