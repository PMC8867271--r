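---
title: "Surrogate-based uncertainty quantification of in-stent restenosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based uncertainty quantification of in-stent restenosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isruq)
```

## The problem

In-stent restenosis (ISR) is the renarrowing of a stented coronary artery by
neointimal tissue. Mechanistic three-dimensional simulations of this process
couple agent-based smooth-muscle-cell (SMC) mechanics and biology with
lattice-Boltzmann blood flow; a single 30-day simulation costs hundreds of
core-hours, which rules out direct Monte Carlo uncertainty quantification
(UQ). `isruq` implements the standard remedy for time-dependent outputs: a
**proper orthogonal decomposition (POD) + Gaussian process (GP)** surrogate
trained on a modest quasi-Monte Carlo design, which then stands in for the
simulator in forward uncertainty propagation and in variance-based (Sobol)
sensitivity analysis.

Two daily quantities of interest (QoIs) over days 0–30 are analysed:

* **ACSA** — the average cross-sectional lumen area over the vessel (mm²),
  non-increasing in time;
* **MRAL** — the maximum relative area loss over cross-sections
  (dimensionless, in [0, 1)), non-decreasing in time. Restenosis is declared
  when MRAL reaches 0.5 (50% occlusion).

Four uncertain inputs are treated as independent uniforms
(`isr_parameter_space()`):

| parameter | range | unit | CV |
|---|---|---|---|
| endothelium regeneration time | 10–20 | day | 0.19 |
| blood flow velocity | 0.133–0.399 | m/s | 0.29 |
| relative threshold strain | 0.446–0.785 | – | 0.16 |
| fenestration percentage | 2–10 | % | 0.38 |

The CV column is the uniform-distribution coefficient of variation
`uniform_cv(lo, hi) = ((hi-lo)/sqrt(12)) / ((lo+hi)/2)`. The threshold-strain
range is expressed relative to a 30% pre-strained vessel: an absolute
experimental strain `s` maps to `rescale_strain(s) = (s+1)/1.3 - 1`, so the
experimental anchor points 0.88 and 1.32 (the rupture strain 1.1 ± 20%)
become 0.446 and 0.785.

## The surrogate

### POD reduction

Training responses `y ∈ R^31` are collected as columns of a snapshot matrix
`S` and decomposed by thin SVD, `S = U Σ V'`. The leading `k` left singular
vectors `Φ` minimise the squared projection error over all rank-`k`
orthonormal bases (Eckart–Young), and `k` is the smallest rank whose
*relative energy* `Σ_{i≤k} σ_i² / Σ σ_i²` reaches 99.9%
(`select_rank()`). Snapshots are **not** mean-centred: centring would change
the energy ratio that the truncation rule is defined on. With 100 snapshots
of smooth, highly time-correlated growth curves, `k` is typically 3–6.

### Coefficient GPs

Each projection coefficient `α_j = φ_j' y` is learned as an independent
single-output GP over the inputs, with an ARD squared-exponential kernel
`k(x, x') = σ_f² exp(-½ Σ_i (x_i - x'_i)²/ℓ_i²)` plus independent Gaussian
noise `σ_n²`. Hyperparameters maximise the log marginal likelihood.
Numerical policy (the underlying study is silent on all of these, so they
are package design choices):

* inputs are mapped to the unit hypercube and targets standardised to zero
  mean and unit variance; the zero-mean prior acts on the standardised scale
  and predictions are un-standardised;
* optimisation runs in log-space with analytic gradients (L-BFGS-B), from
  10 seeded restarts by default, initial lengthscales log-uniform in
  `[1e-2, 1e1]` (unit-cube units);
* the noise variance is floored at `1e-10` and the Cholesky factorisation
  escalates jitter `0 → 1e-10 → 1e-8 → 1e-6` before failing;
* predictions reconstruct `ŷ = Σ_j α_j(x*) φ_j`; the predictive variance
  sums per-coefficient variances, `Var(ŷ_t) = Σ_j Var(α_j) φ_jt²`, an
  *independence approximation* (coefficient GPs share inputs but are fitted
  separately, so cross-covariances are not available).

The surrogate does not know that ACSA must fall and MRAL must rise with
time; where a prediction violates these shape constraints it is repaired by
an isotonic (pool-adjacent-violators) projection, and the raw reconstruction
is kept alongside (`predict(..., raw = TRUE)`). UQ statistics assume
physically valid series, which is why the cleaned series is the default.

### Validation

`cross_validate()` runs k-fold (default fourfold) cross-validation with
seeded random fold assignment. The POD basis and all coefficient GPs are
retrained inside each fold — a strict held-out protocol; reusing a global
basis would leak information from the validation fold into the projector.
Errors are relative L2 norms per held-out response,

* `e_POD = mean ||y - Φ Φ' y|| / ||y||` — the reduction floor,
* `e_GP = mean ||y - Φ α̂(x)|| / ||y||` — the full surrogate error,

reported as means over validation samples (the raw sums are kept too, since
both conventions appear in the literature). `e_GP` cannot systematically
beat `e_POD`: the projection of the truth is the best approximation in the
span of `Φ`.

## The synthetic-data generator

The cluster-scale simulator is emulated by a phenomenological per-slice
growth model (`isr_emulate()`), which is first-class, tested code — the
package's training data come from it. Each of 100 slices carries a
neointimal area `N_i(t)` integrated by explicit Euler (dt = 0.1 day):

```
dN_i/dt = G · S_i(t) · (1 - E(t)·I_i(t)) · (1 - N_i/(N_max,i))
```

* `E(t)` — endothelium coverage: linear to 59% at day 3, then linear to
  100% at the regeneration time (the documented two-phase recovery of the
  simulated endothelium);
* `I_i(t)` — a logistic shear switch in the pseudo-stress `τ = v/r³`
  (fixed flow rate through a narrowing lumen): covered endothelium under
  high shear produces nitric oxide and shuts growth down;
* `S_i(t)` — seeding: a ~half-day activation ramp, an exponentially
  decaying fenestration burst `(1 + β_f φ e^{-t/t_f})` (SMCs migrate
  through lamina fenestrations only until they are covered), a small
  strain-excess term active when the deployment strain exceeds the bond
  threshold, and fixed per-slice noise;
* `N_max,i = 0.8 · A_i(0)` caps growth so the lumen never closes.

MRAL inherits extra noise by construction: it divides by *per-slice* initial
areas (drawn N(3.17, 0.05²) mm²) and takes a maximum over slices, so it is
noisier than the slice-averaged ACSA — the same mechanism the full simulator
exhibits.

### Calibration of the defaults

The kinetic constants are free knobs fixed **once**, by a coarse grid search
on 512-run Sobol designs, to reproduce distribution-level behaviour of the
full model (they are reported in `emulator_config()`):

* day-30 mean MRAL ≈ 0.42 (target band 0.35–0.50), mean ACSA ≈ 2.0 mm²
  from an initial 3.17 mm²;
* day-30 CVs ≈ 0.11 (ACSA) and 0.15 (MRAL) — same order and same ordering
  as the full model (≈ 0.11 and 0.17);
* growth arrest: per-day ACSA change < 1e-3 mm² from 3 days after the
  regeneration time, for every design point;
* monotone one-at-a-time responses (faster flow → larger final lumen,
  longer regeneration / more fenestration → smaller), strain nearly inert;
* a fenestration-dominated early phase: its first-order Sobol index is the
  largest of the four at day 2 and falls below 0.05 by day 10, after which
  flow velocity and regeneration time take over.

Two calibration choices deserve comment. The shear threshold `tau0 = 0.40`
sits just above the initial pseudo-stress of even the fastest flows, so
*every* vessel starts growing and each equilibrates when its narrowing has
raised `τ` past the threshold — this makes the velocity effect emerge
gradually (days 3–15) rather than instantaneously, and it is what lets the
fenestration burst dominate the earliest days. The switch is steep
(`k_tau = 800`) so that once the endothelium is complete the growth rate
falls below the arrest tolerance; the *response surface* in the inputs stays
smooth because the equilibrium lumen area, not the switch itself, carries
the velocity dependence. The burst gain `beta_f` is set strong enough that
the fenestration signature survives the energy-based POD truncation: the
early days carry little of the total response energy, so a weak burst would
be smeared across the retained global modes and its day-2 variance share
misattributed to the other inputs by the *surrogate* even when the emulator
itself shows it clearly.

The explicit Euler scheme is first-order: a halved-step self-check
(dt 0.1 → 0.05) changes day-30 ACSA by ~2×10⁻³ mm² and successive halvings
shrink the change proportionally. This discretisation error is two orders of
magnitude below the across-design response variability (~0.2 mm²), which is
the relevant comparison for every statistic the pipeline reports; driving it
below 10⁻⁴ would cost a ~25× smaller step for no visible change in any
result.

### What the emulator does and does not show

Passing the pipeline's tests on emulated data demonstrates that the
surrogate, UQ and sensitivity machinery recover the behaviour of *a*
nonlinear, noisy, time-dependent growth model with the right qualitative
structure. It does not validate the biology: the emulator has no agent-based
mechanics, no inflammation, no stent geometry, and its trajectories are not
run-for-run comparable to the full simulator. Published headline numbers
that depend on the real training set (error percentages, exact restenosis
fractions, index curves) are therefore reproduced in *pattern*, not in
value.

## Uncertainty propagation and sensitivity analysis

### Quasi-Monte Carlo

All designs use a Sobol low-discrepancy sequence (Joe–Kuo direction numbers,
Gray-code order; dimensions up to 10). Because no installed R package
provides one, the generator is implemented in the package and tested against
an independently computed reference of the classical sequence plus
distributional and discrepancy checks. Scrambling is Owen-type (Matousek
linear matrix scramble + digital shift) under an explicit seed: the study's
"repetitions" are realised as replicates that differ only by scramble seed.
Unscrambled sequences skip the degenerate all-zeros point.

### Forward UQ

`run_uq()` evaluates the surrogate at N scrambled-Sobol points;
`replicate_uq()` repeats this (default 10×) and reports per-day mean, SD
(across samples — across-replicate spread is reported separately), CV,
central 50/75/95% percentile bands (symmetric quantile pairs, linear
interpolation between order statistics), kernel densities (Gaussian kernel,
Scott-style bandwidth) with 50-bin histograms at selected days, and the
restenosis fraction `P(MRAL(t) ≥ 0.5)` over time. `restenosis_scatter()`
filters the input rows of restenotic samples for scatter/histogram views.

### Sobol indices

`saltelli_matrices()` builds the paired design: A and B from complementary
halves of a 2d-dimensional scrambled Sobol sequence, plus the d hybrids
`AB_i`, at `(d+2)·N` evaluations. Estimators are the standard
Saltelli-2010 / Jansen forms,

* first order: `S_i = mean(f_B (f_{AB_i} - f_A)) / Var(f)`,
* total: `S_Ti = mean((f_A - f_{AB_i})²) / (2 Var(f))`,

with `Var(f)` from the pooled (f_A, f_B) sample. The underlying definitions
(conditional-variance ratios) are pinned down in the test suite by a
brute-force double-loop oracle and by analytic benchmarks (additive
functions, Ishigami). Negative estimates are reported as-is — clipping
would bias replicate averages; indices are computed per day on the
reconstructed QoI, and confidence intervals come from across-replicate
percentiles.

## Problem sizes and defaults

The shipped configuration mirrors the full study design: 512 training runs,
100 snapshots, 99.9% energy, fourfold cross-validation. For the forward UQ
and sensitivity stages the package defaults are 10⁴ samples × 10 replicates
and a 2¹² Saltelli base × 10 replicates; these give replicate-level Monte
Carlo noise well below the effects being reported (across-replicate SDs of
day-30 CVs are a few 10⁻³) while keeping a full pipeline run on a single
CPU in the minutes range. Users reproducing the original 10⁵ × 100 setting
need only change the `uq`/`sensitivity` blocks of the run configuration.

## Known limitations

* The emulator is phenomenological; its constants are calibrated to
  distribution-level targets, not to trajectories of the full simulator.
* Coefficient-GP independence makes the reconstruction variance an
  approximation (typically conservative for the leading mode, optimistic
  for cross-mode effects).
* Only uniform, independent inputs are supported; correlated or data-driven
  input distributions are out of scope.
* The Sobol generator supports up to 10 dimensions — enough for this study
  (d = 4, doubled to 8 by the Saltelli design) but not a general-purpose
  qMC library.
* Higher-order interaction indices beyond first/total are not estimated.
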