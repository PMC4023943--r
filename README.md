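# sourcesink

Reconstruction of source–sink dynamics for populations with a passively
dispersed propagule stage — who produced the propagules, where did they
settle, and when were they released — from sink-side abundance surveys
combined with simulated drift trajectories.

The motivating system is scyphozoan jellyfish on a continental shelf: the
benthic polyp colonies (sources) are nearly unobservable, while summer trawl
surveys index the medusae (sinks) as region × year abundance. A particle
drift simulation from an ocean circulation model supplies, for each source
`j`, release event `d`, region `i` and year `t`, the exposure covariate
`G[j,d,i,t]` — the mean fraction of tracked time a propagule spends in the
region. The package fits

```
y[i,t] = Σ_j w[j] · θ[j,i] · Σ_d f[j,d] · G[j,d,i,t] + ε[i,t]
```

with `y` the region-mean `log(CPUE + 1)`, `w[j] ≥ 0` per-source annual
productivity, `θ[j,·] ≥ 0, Σ_i θ[j,i] = 1` sparse sink effects (the source→
region linkage), and `f[j,·] ≥ 0, Σ_d f[j,d] = 1` a smooth release-time
(strobilation) curve on a cubic B-spline basis. Estimation is penalized
constrained least squares with adaptive-lasso-style weights (sparsity in the
sink effects, smoothness of the release curves via coefficient sparsity),
tuned by AIC. Inference: residual bootstrap (zero-probabilities and 90%
intervals per parameter), a permutation test for structural change in the
source-sink dynamics at a given year, and changepoint estimation.
Sensitivity analyses emulate systematic (trajectory shifting) and random
(±5% covariate perturbation) drift-model error. A synthetic drift-world
generator reproduces the study's release design (250 sites, 3 depths, 40
releases/year, 30,000 propagules/year, 8 sink regions) so the whole pipeline
runs with no external data.

## Worked example

```r
library(sourcesink)

cfg   <- demo_design(years = 1:10, sigma = 0.1)   # 2 sources, 4 regions
traj  <- simulate_trajectories(cfg)               # toy advection field
expo  <- compute_exposure(traj, config_partition(cfg), cfg$schedule)
Y     <- simulate_abundance(expo, cfg)
basis <- build_basis(cfg$schedule$n_releases, 4)

om  <- adaptive_weights(Y, expo, basis)$omega
fit <- tune_sourcesink(Y, expo, basis,
                       lambda_grid = c(0, 10^seq(-3, 0, length.out = 7)),
                       omega = om)
fit
#> Source-sink fit: J=2 sources, I=4 regions, T=10 years (K=4 df)
#>   lambda=0  rss=0.519  df=2  AIC=-169.791  converged
#>   productivity w: 1.952 1.078
round(fit$theta, 2)
#>      [,1] [,2] [,3] [,4]
#> [1,] 0.67 0.00 0.33 0.00
#> [2,] 0.00 0.22 0.00 0.78
```

The generating truth in this scenario is `w = (2, 1)`,
`θ = ((0.6, 0, 0.4, 0), (0, 0.3, 0, 0.7))`: the tuned fit recovers the
linkage pattern exactly, with magnitudes within about 0.08 at this noise
level (10 years, σ = 0.1).
`residual_bootstrap()` then attaches zero-probabilities and 90% intervals,
and `fit_table()` prints the reconstruction in the standard layout (one
column block per source; structural zeros — source-region pairs the drift
model never connects — shown as `*`).

A YAML-driven command-line front end covers the same pipeline:
`run("simulate" | "exposure" | "fit" | "bootstrap" | "permtest" |
"changepoint" | "sensitivity-shift" | "sensitivity-perturb" | "report", ...)`,
or `Rscript inst/cli/sourcesink.R <subcommand> --config cfg.yaml`.

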