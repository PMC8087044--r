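# rametipm

Size-structured demographic analysis for clonal, mat-forming plants
surveyed as **ramets** — contiguous clonal units mapped from aerial
(drone) imagery — with invasive *Carpobrotus* populations as the
motivating system. The package is aimed at plant population ecologists and
invasion managers who need to know whether a mapped population is growing,
and which part of the life cycle (survival/growth of established mats
versus sexual reproduction) management should target.

## The model

The state variable is z = log surface area (natural log, m²). A
one-year transition is modelled by an integral projection model (IPM) with
two sub-kernels,

    n(z', t+1) = ∫ [ P(z', z) + F(z', z) ] n(z, t) dz
                  over the size domain [L, U]

with P(z', z) = s(z) g(z'|z) (logistic survival × Gaussian growth whose
SD is σ₀ e^(βσ z), shrinking for large mats) and
F(z', z) = p_r(z) r_s(z) r_r d(z') (logistic flowering × log-linear
quasi-Poisson flower production × recruits-per-flower rate ×
truncated-normal recruit-size density). All vital rates are fitted by
maximum likelihood with AIC selection among intercept-only, linear and
quadratic size dependencies. The kernel is discretised by the midpoint
rule (100 meshpoints by default, with growth densities renormalised on
[L, U] so no probability mass is evicted at the boundaries), and the
asymptotic per-capita growth rate λ is the dominant eigenvalue of the
iteration matrix, with stable size distribution w, reproductive value v,
sensitivity and elasticity kernels, and the sub-kernel elasticity split
e_P + e_F = 1. Uncertainty comes from a stratified nonparametric bootstrap
(resampling time-t records and recruits separately, refitting everything)
and a Gaussian perturbation analysis of the flower-count coefficients.

A synthetic-data generator (`simulate_ramets()`) produces datasets with
exactly this generative structure, so every estimator in the package can
be validated by parameter recovery without any field data.

## Worked example

```r
library(rametipm)

# a study-sized synthetic population (276 ramets) from the published
# vital-rate coefficients
d <- simulate_ramets(reference_params(), 276, seed = 1)
fit <- ipm_fit(d)                               # fit + assemble + analyse
fit <- add_boot_ci(fit, ipm_boot(fit, n_reps = 1000, seed = 2))
fit
#> Ramet integral projection model
#> IPM grid: [-6.825, 4.042], 100 meshpoints, h = 0.108664
#>   lambda = 0.9257 (95% CI 0.881, 0.962)
#>   sub-kernel elasticities: e_P = 0.9991, e_F = 0.0009

fit$fits$growth
#> Vital-rate fit: growth (~ size), n = 199
#>             Estimate Std. Error
#> beta0_g       0.0118     0.0396
#> beta1_g       0.9113     0.0188
#> sigma0_g      0.5007     0.0260
#> betasigma_g  -0.2042     0.0244
#>   logLik = -166.769, AIC = 341.54
```

Reading the output: λ ≈ 0.93 with a CI below 1 means this (simulated)
population would slowly decline under constant conditions; e_P ≈ 0.999
versus e_F ≈ 0.001 says λ is driven almost entirely by survival and
growth of established mats, not by seedling recruitment — the same
qualitative conclusion that makes removal of large ramets the effective
management lever in the real system. The growth fit recovers the
generating coefficients (true values 0.016, 0.898, 0.5, −0.175) within
about one standard error each.

Other entry points: `ipm_from_params()` (model-implied IPM without data),
`mesh_convergence()`, `perturb_flower_model()`, `select_by_aic()`,
`calibrate_sizes()` / `apply_size_correction()` for ground-truth
calibration of imagery-derived areas, `read_ramet_table()` /
`write_ramet_table()` for the CSV schema, `run_pipeline()` +
`report_summary()` (also wrapped by `inst/scripts/ipm-pipeline.R`) for a
config-driven end-to-end run.

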