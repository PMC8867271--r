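# Uncertain-parameter space: the uniform box over the model inputs, unit-cube
# scaling, low-discrepancy sampling, and the two small formulas attached to
# the published parameter table (uniform CV, strain rescaling).

#' Define a box-shaped uncertain parameter space
#'
#' Parameters are modelled as independent uniform random variables on
#' `[min, max]`, the distributional assumption of the restenosis study.
#'
#' @param names character vector of parameter identifiers.
#' @param mins,maxs numeric vectors of lower/upper bounds (`mins < maxs`).
#' @param units optional character vector of unit labels.
#' @return an object of class `param_space`.
#' @seealso [isr_parameter_space()] for the four-parameter restenosis space.
#' @export
parameter_space <- function(names, mins, maxs, units = NULL) {
  check_that(length(names) >= 1L, "a parameter space needs at least one parameter")
  check_that(length(mins) == length(names) && length(maxs) == length(names),
             "names, mins and maxs must have equal length")
  check_that(all(is.finite(mins)) && all(is.finite(maxs)), "bounds must be finite")
  bad <- which(!(mins < maxs))
  check_that(length(bad) == 0L, "min >= max for parameter '%s'", names[bad[1L]])
  if (is.null(units)) units <- rep("", length(names))
  structure(list(names = as.character(names),
                 mins = as.numeric(mins),
                 maxs = as.numeric(maxs),
                 units = as.character(units),
                 d = length(names)),
            class = "param_space")
}

#' The four-parameter uncertain input space of the restenosis study
#'
#' Endothelium regeneration time (10-20 days), blood flow velocity
#' (0.133-0.399 m/s), relative threshold strain for smooth-muscle-cell bond
#' breaking (0.446-0.785, dimensionless, already rescaled for 30% pre-strain)
#' and internal-elastic-lamina fenestration percentage (2-10%), all uniform
#' and independent.
#'
#' @return a `param_space` of dimension 4.
#' @export
#' @examples
#' sp <- isr_parameter_space()
#' uniform_cv(sp$mins[1], sp$maxs[1]) # ~0.19
isr_parameter_space <- function() {
  parameter_space(
    names = c("endothelium_regen_days", "flow_velocity_m_s",
              "threshold_strain", "fenestration_pct"),
    mins  = c(10, 0.133, 0.446, 2),
    maxs  = c(20, 0.399, 0.785, 10),
    units = c("day", "m/s", "", "%")
  )
}

#' @export
print.param_space <- function(x, ...) {
  cat(sprintf("Uniform parameter space (d = %d)\n", x$d))
  tab <- data.frame(parameter = x$names, min = x$mins, max = x$maxs,
                    unit = x$units, cv = round(mapply(uniform_cv, x$mins, x$maxs), 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Map unit-cube points to physical parameter values (and back)
#'
#' Affine scaling between `[0,1]^d` and the box of a [parameter_space()].
#'
#' @param u numeric vector in `[0,1]^d`, or an `n x d` matrix of such points.
#' @param space a `param_space`.
#' @return vector/matrix of the same shape in physical units.
#' @export
scale_unit_to_physical <- function(u, space) {
  stopifnot(inherits(space, "param_space"))
  um <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
  check_that(ncol(um) == space$d, "expected %d columns, got %d", space$d, ncol(um))
  for (j in seq_len(space$d)) {
    bad <- which(um[, j] < 0 | um[, j] > 1)
    check_that(length(bad) == 0L,
               "unit-cube coordinate out of [0,1] for parameter '%s' (row %d)",
               space$names[j], if (length(bad)) bad[1L] else 0L)
  }
  x <- sweep(sweep(um, 2L, space$maxs - space$mins, "*"), 2L, space$mins, "+")
  colnames(x) <- space$names
  if (!is.matrix(u)) x <- drop(x)
  x
}

#' @rdname scale_unit_to_physical
#' @param x physical-unit vector or matrix to map back into the unit cube.
#' @export
scale_physical_to_unit <- function(x, space) {
  stopifnot(inherits(space, "param_space"))
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  check_that(ncol(xm) == space$d, "expected %d columns, got %d", space$d, ncol(xm))
  u <- sweep(sweep(xm, 2L, space$mins, "-"), 2L, space$maxs - space$mins, "/")
  colnames(u) <- space$names
  if (!is.matrix(x)) u <- drop(u)
  u
}

#' Quasi-Monte Carlo sample of a parameter space
#'
#' Draws `n` points of a (optionally scrambled) Sobol sequence and maps them
#' into the physical box.  Replicated studies differ only by
#' `scramble_seed`.
#'
#' @param space a `param_space`.
#' @param n number of samples (>= 1).
#' @param scramble_seed integer seed for the Owen-type scrambling, or `NULL`
#'   for the deterministic unscrambled sequence.
#' @return an `n x d` matrix (columns named after the parameters) with a
#'   `provenance` attribute recording sequence type, seed and skip count.
#' @export
#' @examples
#' head(sobol_samples(isr_parameter_space(), 8, scramble_seed = 1))
sobol_samples <- function(space, n, scramble_seed = NULL) {
  stopifnot(inherits(space, "param_space"))
  check_that(n >= 1, "n must be >= 1, got %s", format(n))
  u <- sobol_sequence(n, space$d, scramble_seed = scramble_seed)
  prov <- attr(u, "sobol")
  x <- scale_unit_to_physical(u, space)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, space$names))
  attr(x, "provenance") <- list(sequence = "sobol",
                                scrambled = prov$scrambled,
                                scramble_seed = prov$scramble_seed,
                                skip = prov$skip)
  x
}

#' Coefficient of variation of a uniform distribution
#'
#' For U(lo, hi): CV = SD / mean = ((hi - lo)/sqrt(12)) / ((lo + hi)/2).
#' Reproduces the CV column of the study's parameter table.
#'
#' @param lo,hi interval endpoints with `lo <= hi` and nonzero midpoint.
#' @return the coefficient of variation (a fraction, not a percentage).
#' @export
#' @examples
#' round(uniform_cv(10, 20), 2) # 0.19
#' round(uniform_cv(2, 10), 2)  # 0.38
uniform_cv <- function(lo, hi) {
  check_that(lo <= hi, "need lo <= hi")
  mu <- (lo + hi) / 2
  check_that(abs(mu) > 0, "CV undefined: interval midpoint is zero")
  ((hi - lo) / sqrt(12)) / mu
}

#' Rescale an absolute tissue strain to the pre-strained configuration
#'
#' Experimental strain measurements start from unstrained arterial samples,
#' while the simulated vessel is pre-strained by 30% through pressurisation.
#' An absolute strain `s` therefore corresponds to a relative strain
#' `(s + 1)/1.3 - 1` of the pre-strained tissue.
#'
#' @param sigma_abso absolute strain (>= 0) from an unstrained reference.
#' @return the equivalent strain relative to the 30% pre-strained state.
#' @export
#' @examples
#' round(rescale_strain(0.88), 3) # 0.446, lower bound of the threshold-strain range
#' round(rescale_strain(1.32), 3) # 0.785, upper bound
rescale_strain <- function(sigma_abso) {
  check_that(all(sigma_abso >= 0), "absolute strain must be nonnegative")
  (sigma_abso + 1) / 1.3 - 1
}
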