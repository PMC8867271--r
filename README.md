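# isruq — surrogate-based uncertainty quantification for in-stent restenosis models

In-stent restenosis (ISR) is the renarrowing of a stented coronary artery by
neointimal tissue growth. Mechanistic 3-D simulations of ISR couple
agent-based smooth-muscle-cell models with lattice-Boltzmann blood flow and
cost hundreds of core-hours per run — far too expensive for Monte Carlo
uncertainty quantification. `isruq` implements the standard workaround for
time-dependent outputs, end to end:

1. **POD + GP surrogate.** Daily quantities of interest (QoIs) over days
   0–30 — the average cross-sectional lumen area (ACSA, mm²) and the maximum
   relative area loss (MRAL, with MRAL ≥ 0.5 defining restenosis) — are
   reduced by proper orthogonal decomposition (thin SVD of a snapshot matrix,
   rank chosen by the 99.9% relative-energy rule `R_en = Σ_{i≤k}σ_i²/Σσ_i²`),
   and each projection coefficient `α_j = φ_j'y` is learned by a Gaussian
   process with ARD squared-exponential kernel
   `k(x,x') = σ_f² exp(−½Σ_i (x_i−x'_i)²/ℓ_i²)` plus noise, fitted by
   marginal-likelihood maximisation. Prediction reconstructs
   `ŷ = Σ_j α_j(x*) φ_j`.
2. **Quasi-Monte Carlo UQ.** Owen-scrambled Sobol sequences propagate the
   four uncertain inputs (endothelium regeneration time, blood flow
   velocity, SMC threshold strain, IEL fenestration percentage; independent
   uniforms) through the surrogate: per-day means, SDs, CVs, percentile
   bands, densities and restenosis fractions, with replication.
3. **Sobol sensitivity analysis.** Saltelli paired designs with
   Saltelli-2010/Jansen estimators give per-day first-order
   (`S_i = Var(E[f|x_i])/Var f`) and total
   (`S_Ti = 1 − Var(E[f|x_∼i])/Var f`) indices with replicate confidence
   intervals.
4. **Synthetic training data.** A phenomenological per-slice neointimal
   growth emulator (`isr_emulate()`) stands in for the cluster-scale
   simulator, reproducing its qualitative dynamics (slow start, near-linear
   growth, arrest after re-endothelialisation, early fenestration-driven
   burst, noisier MRAL than ACSA).

The methods vignette (`vignettes/isruq-methods.Rmd`) documents the model,
the emulator calibration and all numerical policies.

## Worked example

```r
library(isruq)
ds  <- generate_dataset(n = 128, seed = 42)          # emulated training runs
fit <- pod_gp(ds, n_snapshots = 64, restarts = 5, seed = 1)
print(fit)
#> POD + GP surrogate: 128 training runs, 64 snapshots, energy threshold 0.999
#>   acsa: rank k = 2 (energy 0.999777), 2 coefficient GPs
#>   mral: rank k = 2 (energy 0.999587), 2 coefficient GPs

cross_validate(ds, folds = 4, seed = 2, n_snapshots = 64, restarts = 5)
#> Surrogate cross-validation: 4 folds x 1 repetition(s)
#>   acsa: e_POD = 0.01420, e_GP = 0.01446 (mean relative L2 over held-out runs)
#>   mral: e_POD = 0.01817, e_GP = 0.02151 (mean relative L2 over held-out runs)

replicate_uq(fit, N = 2000, reps = 5, master_seed = 3)
#> ACSA:
#>      day_5 day_10 day_15 day_20 day_30
#> mean 2.209  1.958  1.895  1.887  1.887
#> sd   0.135  0.205  0.211  0.213  0.213
#> cv%  6.118 10.480 11.130 11.286 11.287
#> ...
#> restenosis fraction (%):
#>  day_5 day_10 day_15 day_20 day_30
#>   0.00   7.73  16.20  16.73  16.73

sensitivity_over_time(fit, N = 1024, reps = 5, master_seed = 5, qoi = "acsa")
#> First-order indices:
#>                        day_2 day_5 day_10 day_15 day_20 day_30
#> endothelium_regen_days 0.045 0.058  0.090  0.092  0.093  0.093
#> flow_velocity_m_s      0.347 0.864  0.876  0.876  0.876  0.876
#> threshold_strain       0.005 0.002  0.001  0.001  0.001  0.001
#> fenestration_pct       0.590 0.071  0.023  0.021  0.020  0.020
#> Sum of first-order indices at day 30: 0.990
```

Reading the output: the lumen shrinks from 3.17 mm² to a mean of 1.89 mm²
by day 30 with ~11% CV; about 17% of parameter combinations cross the 50%
occlusion threshold; the surrogate reproduces held-out growth curves to
~1.4% (ACSA) / ~2.2% (MRAL) relative L2 error; fenestration dominates the
output variance on day 2 and is negligible from day 10, after which flow
velocity (and increasingly regeneration time) carry it; first-order indices
sum to ≈ 1, so the response is near-additive.

A thin command-line front end wraps the same functions
(`inst/cli/isruq.R`; subcommands `emulate`, `train`, `validate`, `uq`,
`sensitivity`, `report`, `all`), driven by a YAML/JSON configuration — see
`inst/extdata/default_config.yaml`.

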