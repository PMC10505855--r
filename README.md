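# patchforage

Joint Bayesian modelling of foraging patch choice and within-patch
harvest success for trip-level records from mixed cash-subsistence
economies — the setting of contemporary Inuit harvesting, where seasonal
patches (winter floe-edge hunting, spring lake jigging, tidal gathering,
…) differ in cash costs, risk, and reliability, and where gender,
household income, and position in the food-sharing network shape who
pursues what.

The package is aimed at quantitative ecologists and anthropologists who
have (or must emulate) one row per foraging episode and want a fully
reproducible pipeline: data validation, covariate standardization,
network-degree computation, posterior sampling, convergence diagnostics,
and counterfactual prediction, all returning tibbles that compose with
the tidyverse.

## The model

For trip *i* with patch choice *X*ᵢ ∈ {1,…,7} and success *Y*ᵢ ∈ {0,1}:

- **Choice:** *X*ᵢ ~ Categorical(softmax(η<sub>i1</sub>,…,η<sub>i7</sub>)),
  with η<sub>ik</sub> = α<sub>k,season</sub> + γ<sub>k,gender</sub> +
  f<sub>k,age</sub> + βₖᵀxᵢ.
- **Success:** *Y*ᵢ ~ Bernoulli(logit⁻¹(θᵢ)), with
  θᵢ = α̃<sub>Xᵢ,season</sub> + γ̃<sub>Xᵢ,gender</sub> + f̃<sub>age</sub> +
  β̃ᵀxᵢ.

Season-by-patch and gender-by-patch terms are varying intercepts; the
age effects f are latent Gaussian-process vectors over the four ordinal
age classes with squared-exponential covariance
K<sub>ab</sub> = η² exp(−ρ²(a−b)²) + 𝟙<sub>a=b</sub>σ²; covariates x are
standardized household income, sharing-network in- and out-degree, and
group size. One household's missing income is imputed jointly as a
shared latent with Normal(0.5, 1) / half-Cauchy(0, 1) hyper-priors.
Posterior sampling runs through JAGS; the joint log density is also
implemented and oracle-tested in plain R. See the vignette
(`vignettes/patch-choice-model.Rmd`) for the full account.

Because real records of this kind are confidential, the package includes
a synthetic-data module: a deterministic fixture replicating the study
sample's margins (281 trips, 23 harvesters, 13 households, per-patch
counts, 228 men's trips, group-size quartiles 2/3/4, one missing-income
household with 3 hunters and 35 trips, and the household-level
income/degree correlation structure −0.22 / 0.39 / −0.07), plus a fully
generative simulator for parameter-recovery studies.

## Worked example

```r
library(patchforage)

fx <- default_fixture()             # margin-matched synthetic sample
summarize_sample(fx$trips, fx$households)
```

```
Foraging-trip sample: 281 trips, 23 harvesters, 13 households
...
Group-size quantiles (25/50/75%): 2 / 3 / 4

Household-level Pearson correlations:
  pair                       r     n
1 income~in_degree     -0.22      12
2 income~out_degree     0.39      12
3 in_degree~out_degree -0.0727    13
```

The fixture reproduces the anchored sample composition exactly (the
counts are constructed, not sampled) and the correlations within
±0.005. Fitting and predicting — the short chains here keep the demo
fast and *will* trigger the convergence warning; use the defaults
(4 × 1000/1000) for real use:

```r
trips <- standardize_covariates(fx$trips)
fit <- fit_posterior(trips,
  config = fit_config(n_chains = 2, n_warmup = 400, n_draws = 400,
                      seed = 11))
glance(fit)
#>   n_trips n_chains n_draws n_params max_rhat min_ess warn
#> 1     281        2     400      129     2.12    14.0 TRUE

pred <- profile_prediction(fit, profile_preset("adult_low_income"))
pred$summary
#>   patch       choice_mean choice_lo choice_hi success_mean ...
#> 1 winter_inl…     0.314   0.134       0.505          0.715
#> 2 winter_mar…     0.142   0.00576     0.255          0.182
#> 3 spring_inl…     0.426   0.155       0.632          0.771
#> 4 summerautu…     0.00234 0.0000169   0.00476        0.558
#> 5 summerautu…     0.00455 0.0000981   0.00951        0.635
#> 6 tidal           0.0841  0.00438     0.166          0.911
#> 7 incidental      0.0275  0.000319    0.0569         0.837
```

Each row is a patch: the posterior mean and 89% HPD interval of the
probability that this counterfactual harvester (a 40–50-year-old with
low income, 4 incoming and 1 outgoing sharing ties, in the ice season)
chooses the patch, and of success within it. Ice-free patches are
correctly near zero for an ice-season profile; winter marine hunting
shows the low success probability its generative baseline (0.225)
implies. A "poor ice year" counterfactual removes it and reallocates its
mass proportionally:

```r
scenario_patch_removal(fit, profile_preset("adult_low_income"),
                       "winter_marine")$summary
#>   patch               choice_mean
#> 1 winter_inland           0.368
#> 2 winter_marine           0
#> 3 spring_inland           0.492
#> ...
```

`income_sweep()` traces choice/success curves over the observed income
range, `autoplot()`/`plot_income_sweep()` draw the standard panels, and
`parameter_recovery_report()` checks calibration against simulated
ground truth. A thin command-line wrapper with `simulate` / `fit` /
`predict` subcommands ships in `inst/cli/patchforage`.

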