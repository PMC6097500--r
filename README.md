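# lekdyn

Two-scale analysis of lekking-grouse responses to oil-and-gas development
and regional climate.

## What this is for

Wildlife agencies index sage-grouse abundance by spring counts of males on
leks. Two questions recur: how does the areal disturbance from well pads
near a lek affect attendance at that lek, and what does that imply for
whole populations (management units), whose long-run abundance also rides
on inter-decadal climate swings indexed by the Pacific Decadal Oscillation
(PDO)? `lekdyn` implements both scales as one pipeline, for quantitative
ecologists working with lek-count programs, well-pad registries and a
monthly climate index.

At its core are two hierarchical models, fitted by maximum likelihood
(Laplace-marginalized random effects) and by MCMC:

- **Local**: `M[i,y] ~ NegBin(mu[i,y], phi)` with
  `log mu = b0 + bA*AREA[i,y] + bP*PDO[y] + aL[i] + aY[y]`,
  crossed lek and year random effects, `Var(M) = mu + phi*mu^2`.
  AREA is the fraction of a buffer (0.8–6.4 km) covered by 60 m well-pad
  discs, lagged 1–4 years; covariates are standardized, so
  `100*(exp(b)-1)` is the percent effect per SD.
- **Population**: Gompertz dynamics for group density (mean males per
  lek), `log M[g,y] ~ N(b0 + (bD+1+aG[g])*log M[g,y-1] + bA*AREA + bP*PDO
  + aY[y], sigma_eta[g,y])`, process error depending on survey coverage,
  observer error fixed at zero, and carrying capacity
  `log N_inf = -(b0 + bA*AREA + bP*PDO)/(bD + aG[g])`.

Model selection over spatial scales and time lags uses AICc and Akaike
weights (64 local models, 16 population models, common-data rule), with
predictor weights and model averaging over the four-model reduced family.
Fitted effects propagate to population-level impacts on two bases: summed
expected lek counts, and carrying capacity — where weak density
dependence amplifies a small annual effect by `1/|bD|`.

## Worked example

Everything runs on synthetic data; `make_fixture()` writes a complete toy
study (raw lek counts with repeat visits, lek sites, well pads, monthly
index) whose true parameters are known and stored in a manifest.

```r
library(lekdyn)

dir <- tempfile()
make_fixture(seed = 11, dir, n_groups = 3, leks_per_group = 12,
             n_years = 20)
prep <- prepare_data(read_inputs(dir))

## scan 4 radii x 4 area lags x 4 PDO lags = 64 models
scan <- scan_models(prep$lek_years, prep$disturbance, prep$pdo,
                    radii_m = c(800, 1600, 3200, 6400), lags = 1:4)
variable_importance(scan, "radius_m")
#>   level models proportion       weight
#> 3  3200     16       0.25 7.116473e-01
#> 2  1600     16       0.25 2.883509e-01
#> 1   800     16       0.25 1.740105e-06
#> 4  6400     16       0.25 2.121965e-25
variable_importance(scan, "area_lag")[1, ]
#>   level models proportion    weight
#> 1     1     16       0.25 0.9999999
```

The summed Akaike weights put almost all support on the 3.2 km buffer and
a 1-year disturbance lag — which is exactly how the fixture was generated
(the manifest records `true_radius_m: 3200`, `true_area_lag: 1`).

```r
## final local model at the selected scale/lags
des <- build_design(prep$lek_years, prep$disturbance, prep$pdo,
                    3200, area_lag = 1, pdo_lag = 1)
fit <- fit_local(des)
fit_effect_sizes(fit)
#>   predictor        beta    percent      lower      upper
#> 1      area -0.98914086 -62.810393 -67.763434 -57.096335
#> 2       pdo -0.03283355  -3.230038  -9.876885   3.907034
```

A one-SD increase in areal disturbance lowers the expected count at a lek
by ~63% (95% CI 57–68%) — one SD is a lot here because development is
heavily right-skewed across leks, so the per-SD effect is dominated by the
few intensively drilled buffers. The climate effect is small and not
distinguishable from zero on a fixture this size (its true simulated
effect is weak). The population model then runs at the selected scale:

```r
pdes <- build_design(prep$group_density, prep$group_disturbance,
                     prep$pdo, 3200, 1, 1)
pfit <- fit_population(pdes)
carrying_capacity(pfit)$value    # typical group, no disturbance, PDO = 0
#> [1] 17.3765
carrying_capacity_impact(pfit, group_area_raw = 0.01)$percent
#> [1] -5.718922
```

A typical group equilibrates near 17 males per lek; holding 1% mean areal
disturbance in place moves that long-run level by about −6% even though
the annual effect is small — the `1/|bD|` amplification under weak
density dependence.

The whole sequence (prepare → scans → final fits with MCMC → carrying
capacities → impacts → sensitivity suite), with every table written to an
output directory:

```r
cfg <- run_config(input_dir = dir, output_dir = "run1", seed = 3)
run_pipeline(cfg)
```

or from the shell:

```sh
Rscript -e 'lekdyn::lekdyn_cli()' simulate --seed 11 --dir fixture
Rscript -e 'lekdyn::lekdyn_cli()' run-all --config config.json
```

## Documentation

The methods vignette (`vignettes/two-scale-lek-analysis.Rmd`) describes
the models and their assumptions, the numerical choices (Laplace accuracy,
the independence-MH sampler, rounding and standardization conventions),
what the synthetic world does and does not emulate, and known limitations.
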