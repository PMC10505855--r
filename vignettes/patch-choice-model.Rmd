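---
title: "Modelling foraging patch choice and harvest success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling foraging patch choice and harvest success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In Arctic mixed cash-subsistence economies, harvesters choose among
qualitatively different foraging "patches" — seasonal bundles of habitat,
target species and method, such as winter floe-edge seal hunting, spring
lake jigging, or tidal mussel gathering. These patches differ sharply in
required equipment, cash costs, physical risk, and probability of a
successful harvest. `patchforage` implements a joint Bayesian analysis of
trip-level records from such systems: which patch a harvester chose, and
whether the trip succeeded, as functions of gender, age, season, household
income, position in the community food-sharing network, and group size.

The unit of analysis is one foraging episode. For trip $i$ with observed
patch $X_i = k \in \{1,\dots,7\}$ and success indicator $Y_i \in \{0,1\}$:

$$X_i \sim \mathrm{Categorical}(\mathrm{softmax}(\eta_{i1},\dots,\eta_{i7})),
\qquad
\eta_{ik} = \alpha_{k,s_i} + \gamma_{k,g_i} + f_{k,a_i}
          + \boldsymbol\beta_k^\top \mathbf{x}_i,$$

$$Y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\theta_i)),
\qquad
\theta_i = \tilde\alpha_{X_i,s_i} + \tilde\gamma_{X_i,g_i} + \tilde f_{a_i}
         + \tilde{\boldsymbol\beta}^\top \mathbf{x}_i,$$

where $s_i$ is the two-level season (ice vs. ice-free), $g_i$ gender,
$a_i$ one of four ordinal age classes (under 30, 30–40, 40–50, over 50),
and $\mathbf{x}_i$ the standardized covariates: household income,
household in-degree and out-degree in the food-sharing network, and trip
group size. Season and gender enter as patch-indexed varying intercepts;
the patch itself enters the success model only through its intercepts.

## Latent Gaussian-process age effects

Rather than a linear age term, each patch's choice propensity carries a
latent vector $f_{k,\cdot}$ over the four ordered age classes, drawn from
a Gaussian process with squared-exponential covariance on integer
positions $1,\dots,4$:

$$K_{ab} = \eta^2 \exp\{-\rho^2 (a-b)^2\} + \mathbb{1}_{a=b}\,\sigma^2 .$$

$\eta^2$ is the marginal variance of the age effect, $\rho^2$ the inverse
squared length-scale (large $\rho^2$ makes age classes independent, small
$\rho^2$ makes the effect nearly constant in age), and $\sigma^2$ an
independent jitter that also guarantees positive-definiteness. The choice
block uses one hyperparameter triple shared by the seven per-patch age
vectors; the success model has a single shared age vector with its own
triple. Sharing one age curve and one coefficient vector across patches in
the success model is a deliberate parsimony choice: a few hundred trips
cannot identify per-patch success slopes.

## Missing-income imputation

Income is a household-level covariate; one household declines to report
it, which affects all trips by its hunters. The package treats the
missing standardized income as a single latent parameter shared by all of
that household's trips (income is a property of the household, not of the
trip), sampled jointly with everything else:

$$x^{\text{miss}} \sim \mathcal N(\mu_{\text{inc}}, \sigma_{\text{inc}}),
\qquad \mu_{\text{inc}} \sim \mathcal N(0.5, 1),
\qquad \sigma_{\text{inc}} \sim \text{half-Cauchy}(0, 1).$$

An alternative reading — one independent latent per affected trip — is
possible but discards the household-level nature of the variable; the
shared-latent form is the package default and the per-trip variant is not
implemented.

## Priors and identification

Defaults (all exposed through `default_prior_config()` and overridable
from YAML/JSON):

| block | prior | rationale |
|---|---|---|
| varying intercepts, coefficients | $\mathcal N(0, 1)$ | weakly informative on the logit/softmax scale |
| GP scales $\eta^2,\rho^2,\sigma^2$ | half-Cauchy$(0,1)$ | heavy-tailed, keeps mass near small values |
| $\mu_{\text{inc}}$, $\sigma_{\text{inc}}$ | $\mathcal N(0.5,1)$, half-Cauchy$(0,1)$ | imputation hyper-priors |

Two structural decisions deserve comment.

*No reference category.* All seven patch blocks receive zero-centered
priors instead of pinning one patch's parameters to zero. The likelihood
only identifies contrasts, so the priors carry the remaining (harmless)
translation direction; in exchange the prior is exchangeable across
patches, which yields the prior-predictive symmetry below.

*No hard season mask.* The softmax always runs over all seven patches,
with season entering only through the varying intercepts. The mean
prior-predictive probability of choosing any given patch is then exactly
$1/7 \approx 0.14$; a season-masked five/four-way model would give about
$0.22$ instead. Masking remains available (`softmax_probs(mask = )`,
`scenario_patch_removal()`) for counterfactual experiments. These two
facts also give the package its cheapest end-to-end checks: under the
default symmetric priors the Monte-Carlo mean of every patch's
prior-predictive choice probability must be $1/7$ and the mean
prior-predictive success probability must be $1/2$, regardless of the
prior scales. `sample_prior_predictive()` computes both, and the
acceptance script reports them.

## What the synthetic generator emulates — and what it does not

Real trip records of this kind are confidential, so the package ships a
generator with two modes.

`default_fixture()` builds a deterministic, margin-matched sample: 281
trips by 23 harvesters (18 men, 5 women) in 13 households; per-patch trip
counts of 47/38/72/21/75/20/8 (winter inland, winter marine, spring
inland, summer–autumn inland, summer–autumn marine, tidal, incidental);
228 trips by men; group sizes with quartiles 2/3/4; one household with
missing income covering exactly 35 trips by 3 hunters; and a household
table whose income/in-degree, income/out-degree and degree/degree Pearson
correlations are $-0.22$, $0.39$ (over the 12 income-known households)
and $-0.07$ (over all 13), each within $\pm 0.005$. Counts are satisfied
by construction (assignment, then seeded shuffling), not by rejection
sampling, so they hold for every seed. Degrees are solved by a seeded
hill-climb over sum-preserving unit moves (the mean of 4 ties per
household is held exactly — 4 is also the reference value used by the
`reference_adult` profile); incomes are then solved in closed form as a
linear combination of the standardized degree vectors plus an
orthogonalized residual, so the income correlations are exact to
floating-point. Harvester-level facts that no published margin pins down
— the 18/5 gender composition, per-harvester trip counts, the age-class
assignment, which household is the missing-income one — are documented
assumptions, chosen once to be plausible for a purposive sample of active
harvesters. Success flags are drawn from the generative success model
with per-patch baselines reflecting field descriptions of reliability
(tidal gathering 0.90; winter marine 0.225, inside the reported 20–25%
range for floe-edge hunting).

`simulate_trips()` is the fully generative mode: given any
`model_params`, it draws each trip's patch from the softmax choice model
(Gumbel-max categorical sampling) and its success from the logistic model
given the drawn patch, for parameter-recovery experiments with known
ground truth.

What the generator does **not** emulate: spatial structure (toponyms,
travel distances), harvest quantities, species detail, gasoline use,
within-household correlation of unobserved skill, or any real
covariate–outcome relationship beyond those injected through
`default_true_params()`. A green test suite therefore demonstrates that
the pipeline is correct and calibrated on data *shaped like* the study
sample — it says nothing about effect sizes in any real community.

## Inference backend and numerical choices

Posterior sampling uses JAGS (via `rjags`) — conditional slice/Gibbs
updates on exactly the joint density defined by `joint_log_density()`,
which is implemented and tested in R independently of the backend
(brute-force per-row likelihood oracles at tolerance $10^{-10}$; a dense
grid-integration oracle reproduces reduced-model posterior means within
0.05). Choices a maintainer should know about:

* **Softmax stability.** Linear predictors are max-subtracted before
  exponentiation, in R and in the sampler, so $|\eta| \le 700$ cannot
  overflow. Masked patches get probability exactly 0, not a small number.
* **GP conditioning.** Inside the sampler the age covariance receives a
  tiny ridge ($10^{-6}\eta^2 + 10^{-8}$ on the diagonal) so that matrix
  inversion survives jitter values sampled arbitrarily close to zero.
  The R-side `gp_age_cov()` is the pure kernel.
* **Half-Cauchy sampling.** Scale hyperparameters are sampled as
  truncated Cauchy (`dt(0, 1/s^2, 1) T(0,)`) — the direct form suits a
  slice sampler; no log-scale transform is needed.
* **Likelihood clamping.** Success probabilities are clamped to
  $[10^{-15}, 1-10^{-15}]$ inside the Bernoulli log-likelihood, keeping
  it finite for logits beyond $\pm 35$.
* **Quantiles.** All descriptive quantiles use linear interpolation
  between order statistics (`stats::quantile(type = 7)`); the fixture's
  group-size quartile targets are defined under that convention.
* **HPD intervals.** `hpd_interval()` uses the shortest sorted window
  containing $\lceil 0.89\,n \rceil$ draws — deterministic and testable
  by enumeration, unlike density-estimation approaches. Ties are broken
  by the first minimal window.
* **Reproducibility.** Every random step is seeded: the generator from
  `generator_config(seed = )`, each MCMC chain from
  `fit_config(seed = ) + chain`, with explicit RNG types, so identical
  calls give identical tables and draws.
* **Diagnostics.** Split R-hat (each chain halved) and effective sample
  size are computed for every scalar parameter; a fit whose diagnostics
  miss the thresholds (1.01 / 400 by default) is returned with a
  prominent `warn` state rather than silently.

Default chain settings are 4 chains × 1000 warmup + 1000 draws. The test
suite deliberately runs much smaller problems — two chains of a few
hundred iterations on the 281-trip fixture, 60-trip two-patch reductions
for the oracle comparisons, and fabricated delta-mass posteriors for the
prediction algebra — sizes chosen so the whole suite completes in minutes
while still exercising every code path; short chains on the full model
are *expected* to trigger the convergence warning, and the tests assert
the warning machinery rather than suppress it.

## Counterfactual machinery

`profile_prediction()` pushes a covariate profile through every posterior
draw; `income_sweep()` traces choice/success curves along a raw income
grid, refusing to extrapolate beyond the income range observed at fit
time; `scenario_patch_removal()` renormalizes each draw's choice simplex
over a restricted patch set (the "poor ice year" thought experiment:
removed mass reallocates proportionally; success probabilities are
untouched). Raw-valued profile fields ("in-degree: 8") are converted to
the model scale with the covariate scaling stored in the fit. Presets:
`reference_adult` (40–50 years, 4 in-ties, 4 out-ties),
`young_high_income` (under 30, +1 sd income, 8/8 ties; a `_30s` variant
covers the other reading of "young adult"), and `adult_low_income`
(40–50, −1 sd income, 4 in-ties, 1 out-tie). Scenario analysis
renormalizes the fitted softmax rather than refitting under the reduced
choice set; refitting would answer a different (also interesting)
question and can be done by filtering the patch set and calling
`fit_posterior()` again.

## Known limitations

* The slice-sampling backend mixes more slowly per iteration than
  gradient-based samplers on the correlated varying-intercept blocks;
  production analyses should use the default (or larger) chain budgets
  and heed the `warn` state.
* The translation-invariant parameterization leaves one prior-driven
  direction per softmax block; individual coefficients are therefore not
  interpretable in isolation — use contrasts or, better, the prediction
  machinery.
* The fixture's success flags are simulated from `default_true_params()`;
  only the margins and correlation structure, not the stochastic success
  pattern, are anchored to published numbers.
* Observed trips are a selected sample (trips that happened); the model
  describes patch choice conditional on going out, not latent preference.
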