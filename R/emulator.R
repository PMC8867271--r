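# Phenomenological neointimal growth emulator.
#
# A desk-scale stand-in for the cluster-scale three-dimensional restenosis
# simulator: each of n_slices lumen cross-sections carries a neointimal area
# N_i(t) growing by a logistic-capped rate that is seeded early (migration
# through lamina fenestrations, strain-induced microfractures), inhibited by
# nitric oxide wherever the regrowing endothelium is covered AND wall shear
# stress is high, and frozen once re-endothelialisation completes.  The two
# daily quantities of interest are the slice-average lumen area (ACSA, mm^2)
# and the maximum relative area loss over slices (MRAL, dimensionless).

#' Configuration of the neointimal growth emulator
#'
#' Geometry, kinetic constants and noise scales of the per-slice growth
#' model.  The defaults are a fixed calibration chosen so that a 512-run
#' quasi-Monte Carlo design over [isr_parameter_space()] reproduces the
#' qualitative behaviour of the full simulator: slow start, near-linear
#' growth over days 1-10, growth arrest within ~3 days of the endothelium
#' regeneration time, day-30 mean maximum relative area loss around 0.4,
#' and a noisier MRAL than ACSA.
#'
#' @param n_slices number of lumen cross-sections along the 18 mm vessel.
#' @param initial_area_mean,initial_area_sd per-slice post-stenting lumen
#'   area distribution (mm^2); 3.17 mm^2 matches the simulator's
#'   post-deployment state.
#' @param horizon simulated duration in days.
#' @param dt explicit-Euler step (days); must divide 1.
#' @param G maximum neointimal growth rate (mm^2/day).
#' @param N_frac_max cap on neointimal area as a fraction of the initial
#'   slice area (< 1, so the lumen never closes).
#' @param tau0,k_tau midpoint and steepness of the logistic shear-stress
#'   inhibition switch (pseudo-stress units v/r^3).
#' @param beta_f,t_f gain (per percentage point of fenestration) and decay
#'   time (days) of the early fenestration-driven seeding burst.
#' @param beta_eps,eps_dep gain of the strain-excess seeding term and the
#'   fixed deployment strain it is compared against.
#' @param growth_noise_sd SD of the multiplicative per-slice growth noise.
#' @return an object of class `emulator_config`.
#' @export
emulator_config <- function(n_slices = 100L,
                            initial_area_mean = 3.17,
                            initial_area_sd = 0.05,
                            horizon = 30L,
                            dt = 0.1,
                            G = 0.28,
                            N_frac_max = 0.8,
                            tau0 = 0.40,
                            k_tau = 800,
                            beta_f = 0.35,
                            t_f = 0.8,
                            beta_eps = 0.3,
                            eps_dep = 0.6,
                            growth_noise_sd = 0.05) {
  cfg <- list(n_slices = as.integer(n_slices),
              initial_area_mean = initial_area_mean,
              initial_area_sd = initial_area_sd,
              horizon = as.integer(horizon), dt = dt,
              G = G, N_frac_max = N_frac_max,
              tau0 = tau0, k_tau = k_tau,
              beta_f = beta_f, t_f = t_f,
              beta_eps = beta_eps, eps_dep = eps_dep,
              growth_noise_sd = growth_noise_sd)
  num <- unlist(cfg)
  check_that(all(is.finite(num)) && all(num > 0 | names(num) == "growth_noise_sd" & num >= 0),
             "all emulator constants must be positive (growth_noise_sd >= 0)")
  steps_per_day <- 1 / dt
  check_that(abs(steps_per_day - round(steps_per_day)) < 1e-9, "dt must divide 1 day")
  check_that(N_frac_max < 1, "N_frac_max must be < 1")
  structure(cfg, class = "emulator_config")
}

#' @export
print.emulator_config <- function(x, ...) {
  cat("Neointimal growth emulator configuration\n")
  cat(sprintf("  %d slices, A0 ~ N(%.3g, %.3g^2) mm^2, %d days at dt = %g\n",
              x$n_slices, x$initial_area_mean, x$initial_area_sd, x$horizon, x$dt))
  cat(sprintf("  G = %g mm^2/day, cap %g, shear switch (tau0 = %g, k = %g)\n",
              x$G, x$N_frac_max, x$tau0, x$k_tau))
  cat(sprintf("  fenestration burst (beta_f = %g/%%, t_f = %g d), strain (beta_eps = %g, eps_dep = %g), noise SD %g\n",
              x$beta_f, x$t_f, x$beta_eps, x$eps_dep, x$growth_noise_sd))
  invisible(x)
}

#' Endothelium coverage over time
#'
#' Piecewise-linear re-endothelialisation: coverage rises to 59% over the
#' first 3 days, then linearly to 100% at the regeneration time `T_regen`,
#' and stays complete thereafter.
#'
#' @param t time in days (vectorised, >= 0).
#' @param T_regen endothelium regeneration time in days (> 3).
#' @return coverage fraction in `[0, 1]`.
#' @export
#' @examples
#' endothelium_coverage(3, 15)  # 0.59
#' endothelium_coverage(15, 15) # 1
endothelium_coverage <- function(t, T_regen) {
  check_that(all(t >= 0), "t must be nonnegative")
  check_that(T_regen > 3, "T_regen must exceed the 3-day fast-recovery phase")
  ifelse(t <= 3, 0.59 * t / 3,
         ifelse(t <= T_regen, 0.59 + 0.41 * (t - 3) / (T_regen - 3), 1))
}

#' Shear-stress growth inhibition
#'
#' Wall shear stress scales as `v / r^3` for fixed flow rate through a
#' narrowing lumen of radius `r = sqrt(area/pi)`; sufficiently high shear
#' drives nitric-oxide production in covered endothelium, inhibiting
#' smooth-muscle-cell proliferation.  Modelled as a logistic switch in the
#' pseudo-stress `tau = v / r^3`.
#'
#' @param v blood flow velocity (m/s, > 0), vectorised.
#' @param area lumen cross-sectional area (mm^2, > 0), vectorised.
#' @param config an [emulator_config()] supplying `tau0` and `k_tau`.
#' @return inhibition fraction in (0, 1), increasing in `v`, decreasing in
#'   `area`.
#' @export
shear_inhibition <- function(v, area, config = emulator_config()) {
  check_that(all(v > 0), "velocity must be positive")
  check_that(all(area > 0), "area must be positive")
  r <- sqrt(area / pi)
  tau <- v / r^3
  stats::plogis(config$k_tau * (tau - config$tau0))
}

#' Simulate per-slice lumen areas under one parameter vector
#'
#' Integrates, per slice i, the neointimal area ODE
#' `dN_i/dt = G * S_i(t) * (1 - E(t) * I_i(t)) * (1 - N_i / (N_frac_max * A_i(0)))`
#' by explicit Euler at step `dt`, where `E(t)` is [endothelium_coverage()],
#' `I_i(t)` is [shear_inhibition()] at the current slice area, and the
#' seeding factor
#' `S_i(t) = (1 - exp(-t/0.5)) * (1 + beta_f * phi * exp(-t/t_f)) *
#' (1 + beta_eps * max(0, eps_dep - eps_thr)) * (1 + eta_i)`
#' combines the initial proliferation ramp, the decaying fenestration burst,
#' strain-excess seeding and fixed per-slice noise `eta_i`.
#'
#' @param params parameter vector in physical units, ordered as in
#'   [isr_parameter_space()] (regeneration days, velocity, threshold strain,
#'   fenestration percentage).
#' @param config an [emulator_config()].
#' @param seed integer seed fixing the slice-level randomness.
#' @return a `lumen_series`: `n_slices x (horizon+1)` matrix of daily areas
#'   (mm^2) with attribute `A0` (initial areas).
#' @export
isr_emulate <- function(params, config = emulator_config(), seed = 1L) {
  params <- as.numeric(params)
  check_that(length(params) == 4L, "expected 4 parameters, got %d", length(params))
  T_regen <- params[1L]; v <- params[2L]; eps_thr <- params[3L]; phi <- params[4L]
  check_that(T_regen > 3, "regeneration time must exceed 3 days")
  check_that(v > 0 && phi > 0 && eps_thr > 0, "parameters must be positive")
  ns <- config$n_slices
  draws <- with_seed(seed, {
    list(A0 = stats::rnorm(ns, config$initial_area_mean, config$initial_area_sd),
         eta = stats::rnorm(ns, 0, config$growth_noise_sd))
  })
  A0 <- pmax(draws$A0, 0.1 * config$initial_area_mean)
  eta <- pmax(draws$eta, -0.9)
  Nmax <- config$N_frac_max * A0
  strain_gain <- 1 + config$beta_eps * max(0, config$eps_dep - eps_thr)
  nt <- config$horizon + 1L
  steps_per_day <- round(1 / config$dt)
  A <- matrix(NA_real_, nrow = ns, ncol = nt)
  A[, 1L] <- A0
  N <- numeric(ns)
  t <- 0
  for (day in seq_len(config$horizon)) {
    for (s in seq_len(steps_per_day)) {
      Acur <- A0 - N
      E <- endothelium_coverage(t, T_regen)
      inhib <- shear_inhibition(v, Acur, config)
      S <- (1 - exp(-t / 0.5)) *
        (1 + config$beta_f * phi * exp(-t / config$t_f)) *
        strain_gain * (1 + eta)
      dN <- config$G * S * (1 - E * inhib) * (1 - N / Nmax)
      N <- pmin(N + config$dt * dN, Nmax)
      t <- t + config$dt
      if (any(!is.finite(N))) {
        stop(sprintf("emulator integration produced non-finite state at t = %.3f (day %d, step %d)",
                     t, day, s), call. = FALSE)
      }
    }
    A[, day + 1L] <- A0 - N
  }
  structure(A, A0 = A0, class = c("lumen_series", "matrix"))
}

#' Average cross-sectional lumen area (ACSA)
#'
#' Mean lumen area over slices at each day.
#'
#' @param ls a `lumen_series` from [isr_emulate()] (or any slices-by-days
#'   area matrix).
#' @return numeric vector of daily ACSA values (mm^2) with attribute
#'   `qoi = "acsa"`.
#' @export
compute_acsa <- function(ls) {
  check_that(is.matrix(ls) && all(is.finite(ls)), "lumen series must be a finite matrix")
  structure(colMeans(ls), qoi = "acsa")
}

#' Maximum relative area loss (MRAL)
#'
#' Worst-case per-slice fraction of initial lumen area lost at each day:
#' `max_i (1 - A_i(t) / A_i(0))`.  Restenosis is conventionally declared
#' when this exceeds 0.5.
#'
#' @param ls a `lumen_series` from [isr_emulate()].
#' @return numeric vector of daily MRAL values in `[0, 1)` with attribute
#'   `qoi = "mral"`.
#' @export
compute_mral <- function(ls) {
  check_that(is.matrix(ls) && all(is.finite(ls)), "lumen series must be a finite matrix")
  A0 <- attr(ls, "A0")
  if (is.null(A0)) A0 <- ls[, 1L]
  check_that(all(A0 > 0), "initial areas must be positive")
  loss <- 1 - sweep(ls, 1L, A0, "/")
  structure(apply(loss, 2L, max), qoi = "mral")
}

#' Generate a training dataset from the emulator
#'
#' Draws a scrambled-Sobol design of `n` parameter vectors and runs the
#' emulator once per design point, with per-run seeds derived
#' deterministically from the master seed.
#'
#' @param space a `param_space` (default the restenosis space).
#' @param n number of runs.
#' @param config an [emulator_config()].
#' @param seed master integer seed (controls design scrambling and all runs).
#' @return an `isr_dataset`: list with `samples` (`n x d`), `acsa` and
#'   `mral` (`n x (horizon+1)` daily QoI matrices) and `provenance`.
#' @export
#' @examples
#' ds <- generate_dataset(n = 8, seed = 1)
#' dim(ds$acsa)
generate_dataset <- function(space = isr_parameter_space(), n,
                             config = emulator_config(), seed = 1L) {
  check_that(n >= 1, "n must be >= 1")
  X <- sobol_samples(space, n, scramble_seed = derive_seed(seed, 1L))
  nt <- config$horizon + 1L
  acsa <- matrix(NA_real_, n, nt)
  mral <- matrix(NA_real_, n, nt)
  run_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, 1000L + i), integer(1L))
  for (i in seq_len(n)) {
    ls <- isr_emulate(X[i, ], config, seed = run_seeds[i])
    acsa[i, ] <- compute_acsa(ls)
    mral[i, ] <- compute_mral(ls)
  }
  colnames(acsa) <- colnames(mral) <- sprintf("day_%02d", 0:(nt - 1L))
  structure(list(samples = X, acsa = acsa, mral = mral,
                 space = space, config = config,
                 provenance = list(master_seed = as.integer(seed),
                                   design_seed = derive_seed(seed, 1L),
                                   run_seeds = run_seeds)),
            class = "isr_dataset")
}

#' @export
print.isr_dataset <- function(x, ...) {
  cat(sprintf("Emulated restenosis dataset: %d runs x %d days (+day 0)\n",
              nrow(x$samples), ncol(x$acsa) - 1L))
  cat(sprintf("  day-30 ACSA mean %.3f mm^2, MRAL mean %.3f\n",
              mean(x$acsa[, ncol(x$acsa)]), mean(x$mral[, ncol(x$mral)])))
  invisible(x)
}
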