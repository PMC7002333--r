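# snowsync

Spatiotemporal modelling and spatial synchrony of snow-track census
counts.

## What this package is for

National snow-track monitoring schemes count animal tracks crossing
triangular transects (12-km perimeter in forest, 6-km in farmland
mosaic) after fresh snowfall. Counts per km of census line index winter
abundance of boreal mammals — here, the red squirrel and its pine-marten
and goshawk predators — but only a changing subset of transects is
censused each winter, and abundance fluctuates jointly over hundreds of
kilometres, driven by masting spruce cone crops and weather. `snowsync`
is for ecologists who want to analyse such data (or stress-test the
analysis itself) with:

* a **hierarchical negative-binomial count model** with a latent
  separable Matérn × AR1 Gaussian field,
* a **flat-top Gaussian predation-pressure kernel** around raptor nests
  with AIC-based shape selection,
* **covariate preparation**: thin-plate-spline cone-crop surfaces with
  failure-year zero imputation, track densities, lags, and 2-SD
  covariate scaling,
* **per-year Moran's I correlograms** for model-free spatial synchrony,
* a **seeded synthetic-data generator** reproducing the survey's
  generative structure, so the whole pipeline is testable end to end.

## The model

For transect *i* (perimeter `L_i` km, location `s_i`) in winter *t*:

```
y_it ~ NB(mu_it, alpha),        Var(y) = mu + mu^2 / alpha
log mu_it = log L_i + beta' x_it + w(s_i, t)
Cov{w(s,t), w(s',t')} = sigma^2 * (kappa d) K_1(kappa d) * rho^|t-t'|,
kappa = sqrt(8) / range
```

Covariates (marten density, predation kernel, cone index, transect
type, previous-day temperature and precipitation) are centred and
scaled by two standard deviations so weights are mutually comparable.
The *range* is the distance at which the spatial correlation falls to
≈ 0.14. Hyperparameters are estimated by empirical Bayes (maximised
Laplace-approximate marginal likelihood, sparse Kronecker precision);
the latent posterior is a Gaussian at the joint mode, refined by
importance-reweighted draws. Models are ranked by WAIC. See the
vignette (`vignettes/spatiotemporal-snow-tracks.Rmd`) for the full
methodological account.

## Worked example

The demo pipeline simulates a reduced-scale study (85 transects, 8
winters, short 150-km range), selects no kernel (uses the default
shape), builds covariates, fits the model ladder, and ranks by WAIC:

```r
library(snowsync)
report <- run_pipeline(demo_config(seed = 42, n_draws = 150))
print(report)
#> Model ranking (lower WAIC is better):
#>            model spatial temporal n_covariates     waic
#>  c_st_covariates  matern      ar1            6 1677.653
#>   b_st_smoothing  matern      ar1            0 1704.473
#>    a_independent    none     none            6 1737.500
#> Best model: c_st_covariates
#> Spatial range: 75 km (SD 27)
```

The spatiotemporal model with covariates wins (lowest WAIC), the
smoothing-only model is second, the independent regression last — the
qualitative ordering such data are built to produce. The recovered
posterior summaries sit on top of the generative weights:

```r
print(report$coefficients, digits = 2)
#>             name     mean   sd    q2.5  median  q97.5   mode
#> 1    (Intercept) -1.80567 0.15 -2.1185 -1.8040 -1.507 -1.803
#> 2 marten_density  0.19425 0.10 -0.0089  0.1931  0.415  0.181
#> 3 goshawk_kernel  0.00065 0.12 -0.2488  0.0012  0.236  0.024
#> 4     cone_index  0.46794 0.12  0.2283  0.4628  0.707  0.477
#> 5  triangle_type -0.58681 0.15 -0.8878 -0.5974 -0.308 -0.593
#> 6    temperature  0.39739 0.13  0.1603  0.3955  0.707  0.397
#> 7  precipitation -0.17463 0.11 -0.3961 -0.1912  0.038 -0.171
```

(The generator used intercept −1.73, marten 0.22, goshawk 0.11, cones
0.37, type −0.57, temperature 0.30, precipitation −0.24; at this small
scale the weakest weight — the kernel — is not separable from noise,
which is exactly what its wide interval says.) The estimated spatial
range, 75 km (truth 150 km), carries a large SD at 85 sites; range
recovery sharpens with the site count, as the acceptance study below
shows. `report$correlogram` holds the per-year Moran's I table for the
squirrel track densities.

Individual stages are plain functions: `simulate_dataset()`,
`select_kernel_params()`, `kernel_covariate()`, `build_cone_index()`,
`assemble_design()`, `fit_st_model()`, `waic()`, `extract_range()`,
`predict_surface()`, `spatial_residuals()`, `correlogram()`.

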