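test_that("endothelium coverage follows the two-phase linear recovery", {
  expect_equal(endothelium_coverage(0, 15), 0)
  expect_equal(endothelium_coverage(3, 15), 0.59)
  expect_equal(endothelium_coverage(15, 15), 1)
  expect_equal(endothelium_coverage(20, 15), 1)
  # midpoint of the second ramp
  expect_equal(endothelium_coverage(9, 15), 0.59 + 0.41 * 0.5)
  expect_error(endothelium_coverage(1, 2), "3-day")
})

test_that("shear inhibition is a monotone logistic switch in v and area", {
  cfg <- emulator_config()
  a <- 3.17
  expect_gt(shear_inhibition(0.4, a, cfg), shear_inhibition(0.2, a, cfg))
  expect_gt(shear_inhibition(0.3, 2.0, cfg), shear_inhibition(0.3, 3.0, cfg))
  # logistic midpoint: tau == tau0
  r3 <- (sqrt(a / pi))^3
  v_mid <- cfg$tau0 * r3
  expect_equal(shear_inhibition(v_mid, a, cfg), 0.5, tolerance = 1e-12)
  # steep-switch limit
  cfg_step <- emulator_config(k_tau = 1e6)
  expect_equal(shear_inhibition(v_mid * 1.05, a, cfg_step), 1, tolerance = 1e-6)
})

test_that("zero growth rate freezes the lumen and areas never increase", {
  p <- midpoint_params()
  frozen <- isr_emulate(p, small_config(G = 1e-12), seed = 1)
  expect_lt(max(abs(sweep(frozen, 1, frozen[, 1], "-"))), 1e-9)
  ls <- isr_emulate(p, small_config(), seed = 1)
  expect_true(all(diff(t(ls)) <= 1e-12))
  expect_true(all(ls > 0))
})

test_that("emulator runs are deterministic given the seed", {
  p <- midpoint_params()
  expect_identical(isr_emulate(p, small_config(), seed = 7),
                   isr_emulate(p, small_config(), seed = 7))
  expect_false(identical(isr_emulate(p, small_config(), seed = 7),
                         isr_emulate(p, small_config(), seed = 8)))
})

test_that("growth arrests near the regeneration time at midpoint parameters", {
  p <- midpoint_params() # T_regen = 15
  acsa <- compute_acsa(isr_emulate(p, emulator_config(), seed = 2))
  late <- acsa[(15 + 3 + 1):31]
  expect_lt(max(abs(diff(late))), 1e-3)
})

test_that("the explicit-Euler discretisation converges at first order", {
  p <- midpoint_params()
  a <- vapply(c(0.1, 0.05, 0.025), function(dt)
    tail(compute_acsa(isr_emulate(p, small_config(dt = dt), seed = 3)), 1), numeric(1))
  d1 <- abs(a[1] - a[2])
  d2 <- abs(a[2] - a[3])
  # successive halvings shrink the change ~2x (O(dt)), and the absolute
  # step error stays far below the across-design variability (~0.2 mm^2)
  expect_lt(d1, 5e-3)
  expect_lt(d2, 0.75 * d1)
})

test_that("QoI reductions match their definitions", {
  ls <- structure(rbind(c(3, 3, 3), c(4, 4, 4)), A0 = c(3, 4),
                  class = c("lumen_series", "matrix"))
  expect_equal(unname(as.numeric(compute_acsa(ls))), c(3.5, 3.5, 3.5))
  ls2 <- structure(rbind(c(3, 3 * 0.4), c(4, 4 * 0.7)), A0 = c(3, 4),
                   class = c("lumen_series", "matrix"))
  expect_equal(as.numeric(compute_mral(ls2)), c(0, 0.6))
  # MRAL is non-decreasing on any emulator run
  m <- compute_mral(isr_emulate(midpoint_params(), small_config(), seed = 5))
  expect_true(all(diff(m) >= -1e-12))
  expect_true(all(m >= 0 & m < 1))
})

test_that("day-30 responses are monotone in each input, strain weakest", {
  sp <- isr_parameter_space()
  mid <- midpoint_params(sp)
  final_acsa <- function(p) tail(compute_acsa(isr_emulate(p, emulator_config(), seed = 42)), 1)
  effects <- numeric(4)
  signs <- numeric(4)
  for (j in 1:4) {
    grid <- seq(sp$mins[j], sp$maxs[j], length.out = 7)
    vals <- vapply(grid, function(g) { p <- mid; p[j] <- g; final_acsa(p) }, numeric(1))
    expect_true(all(diff(vals) <= 1e-9) || all(diff(vals) >= -1e-9),
                label = sprintf("monotone response in %s", sp$names[j]))
    effects[j] <- diff(range(vals))
    signs[j] <- sign(vals[7] - vals[1])
  }
  expect_equal(signs[1], -1) # longer regeneration -> smaller lumen
  expect_equal(signs[2], 1)  # faster flow -> larger lumen
  expect_equal(signs[4], -1) # more fenestration -> smaller lumen
  expect_lt(effects[3], min(effects[-3])) # strain nearly inert
})

test_that("generated datasets have the right shape, determinism and noise ordering", {
  ds <- small_dataset()
  n <- nrow(ds$samples)
  expect_equal(dim(ds$samples), c(n, 4))
  expect_equal(dim(ds$acsa), c(n, 31))
  expect_equal(dim(ds$mral), c(n, 31))
  ds2 <- generate_dataset(n = 8, config = small_config(), seed = 123)
  ds3 <- generate_dataset(n = 8, config = small_config(), seed = 123)
  expect_identical(ds2$acsa, ds3$acsa)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(ds$mral[, 31]), cv(ds$acsa[, 31])) # MRAL noisier than ACSA
})
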