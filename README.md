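# bsir — scalable Bayesian image-on-scalar regression

`bsir` fits fully Bayesian group-level regressions of image-valued
responses (task-fMRI contrast maps, surface statistics) on participant
scalars, for analysts who want voxel-level effect estimates *and*
calibrated evidence maps instead of mass-univariate t-maps.  For
participant *i* and location *s_v* it models

    y_i(s_v) = Σ_j x_ij α_j + Σ_j x_ij β_j(s_v) + η_i(s_v) + ε_i(s_v),
    ε_i ~ GP(0, σ²_ε K),   β_j ~ GP(0, σ²_β K),   η_i ~ GP(0, σ²_η K),

with a shared Matérn kernel K, half-Cauchy priors (scale A = 100) on all
standard deviations via the conjugate inverse-gamma mixture, and the
identifiability constraints Σ_i η_i(s_v) = 0, Σ_v β_j(s_v) = 0.  A Nyström
low-rank approximation K ≈ ΨΛΨᵀ from L inducing points and a
Karhunen–Loève reparameterization reduce inference to L (and L_η ≈ 0.1·L)
basis coefficients per field; projecting the images with Φ = ΨΛ^(−1/2)
whitens the GP noise, so every posterior update touches only small
matrices.  Two engines fit the same model: a conjugate multi-chain Gibbs
sampler and a mean-field coordinate-ascent variational approximation
(typically sub-second at L ≈ 150).  Voxel effects α_j + β_j(s_v) are
summarized by posterior means, credible intervals, the posterior
probability of a positive effect P⁺, and the evidence score
Es = 2(P⁺ − ½) ∈ [−1, 1], thresholded at |Es| > 0.95 for activation maps;
massive-univariate GLM (+ Benjamini–Hochberg) and voxelwise Bayesian
multilevel (BML) baselines, a leave-one-out procedure for choosing L,
posterior predictive checks, a synthetic-data generator, and NIfTI I/O
round out the toolkit.

## Worked example

Simulate a slice-level study (two-region sparse truths, SNR 0.3 at
σ_ε = 2), fit with the variational engine, and score against the truth:

```r
library(bsir)
mask  <- sim_mask(2000, seed = 1)
truth <- sim_truth(mask, sigma_eps = 2, snr = 0.3, seed = 1)
dat   <- sim_dataset(truth, N = 50, seed = 2)

fit <- bsir(~ x, data = dat$data, images = dat$Y, domain = mask,
            kernel = matern_kernel(0.1), L = 120, engine = "vi",
            standardize = FALSE, seed = 1)
fit
#> Bayesian image-on-scalar regression fit
#>   50 participants, 1999 locations, 1 covariate(s) + intercept
#>   basis: L = 120, L_eta = 12; kernel length scale 0.1
#>   engine: VI, 500 sweeps, ELBO -13645.5282 (max_iter reached)

summary(fit)
#> Voxel-level effect summaries (vi engine, 95% intervals, |Es| > 0.95 two-sided)
#>   (Intercept)  mean range [-4.213, 4.513], 255/1999 active locations
#>   x            mean range [-4.160, 4.400], 217/1999 active locations
```

The summary holds, per covariate, the posterior mean and SD map, the
equal-tailed 95% interval, P⁺, Es, and the activation mask; `coef()`
returns the posterior-mean voxel-effect matrix, `predict()` images for
new covariate rows, `simulate()`/`posterior_predictive()` replicate
datasets for model checking, and `plot()` draws the maps.  Scoring this
fit against the generator's truth:

```r
s <- summary(fit)
effect_metrics(sapply(s$effects, `[[`, "mean"), truth$beta,
               sapply(s$effects, `[[`, "es"),
               sapply(s$effects, `[[`, "lower"),
               sapply(s$effects, `[[`, "upper"), truth$active)
#> MSE 0.070 | TPR 0.68 | FDR 0.18 | coverage 0.954
```

so at this small size the model recovers the effect maps with 95%-interval
coverage slightly above nominal; the elevated FDR of Es-thresholding
against exactly-zero truths is a known structural behavior discussed in
the methods vignette.  `choose_L()` selects the basis size by the 80–98%
cumulative-variance window plus leave-one-out predictive error;
`glm_voxelwise()`, `bml_voxelwise()` and `run_simulation_study()`
reproduce the baseline comparisons.  A command-line pipeline
(`exec/bsir`: `simulate`, `select-L`, `fit`, `summarize`, `ppc`,
`predict`, `simstudy`) drives the same functions from files.

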