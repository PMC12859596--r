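---
title: "Hurdle-Poisson disease mapping: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurdle-Poisson disease mapping: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rare-event mortality analysed at high spatio-temporal resolution — for
example suicide deaths per mid-size census area per year, where a typical
area of 5,000–15,000 residents expects roughly one event per year — produces
count tables dominated by zeros. Aggregating space or time away hides
exactly the local structure such analyses are meant to reveal. `hpmap`
instead models the zeros explicitly with a two-component *hurdle* model
inside a Bayesian hierarchical disease-mapping framework, and provides every
step around it: indirect standardisation, a synthetic-data generator with
known ground truth, MCMC inference, and the standard reporting quantities
(relative-risk surfaces, exceedance probabilities, per-SD covariate effects,
variance decomposition, covariate profiles along the risk ranking).

# The model

Let $y_{it}$ be the event total in area $i$ and year $t$, and $E_{it}$ the
age-sex indirectly standardised expected count (computed from pooled
whole-panel reference rates, so $\sum E = \sum y$ by construction). The
observation model is a hurdle:

* occurrence (gate): $z_{it} = \mathbb{1}[y_{it} \ge 1] \sim
  \mathrm{Bernoulli}(\pi_{it})$, $\operatorname{logit}(\pi_{it}) = \eta^b_{it}$;
* positive counts: $y_{it} \mid y_{it} \ge 1 \sim
  \mathrm{ZTPoisson}(\mu_{it})$, $\log \mu_{it} = \eta^p_{it}$,

with the zero-truncated Poisson pmf $\mu^k e^{-\mu} / (k!\,(1 - e^{-\mu}))$,
$k \ge 1$. The linear predictors are

$$\eta^p_{it} = \log E_{it} + \alpha_p + x_i^\top \beta_p + b_i + \gamma_t +
\varphi_t + \psi_{it},$$
$$\eta^b_{it} = \alpha_b + x_i^\top \beta_b + \delta_s b_i + \delta_t(\gamma_t +
\varphi_t) + \delta_{st} \psi_{it},$$

where $x_i$ are standardised area-level covariates (so $\beta$ is a per-SD
log-risk effect), $b$ is a BYM2 spatial effect, $\gamma$ a first-order
random-walk temporal trend, $\varphi$ an exchangeable year effect, and
$\psi$ an exchangeable (Type I) space-time interaction. The offset enters
the count component only. The occurrence component borrows each latent field
scaled by its own sharing coefficient $\delta$, the canonical
shared-component construction when two likelihood components are believed to
reflect one underlying risk surface. Each component carries its own
covariate coefficient vector.

The BYM2 effect is parameterised non-centred,
$b = \sigma_b(\sqrt{1-\phi}\,v + \sqrt{\phi}\,u)$, with $v$ unit white
noise and $u$ a scaled ICAR field (precision $s\,(D - W)$, where the scaling
$s$ is the geometric mean of the marginal variances of the constrained
intrinsic field, so $\sigma_b$ has a common interpretation across graphs).
The RW1 trend is scaled the same way. Sum-to-zero constraints hold for $u$
within each graph component and for $\gamma$ overall; areas without
neighbours receive purely unstructured variance.

## Priors and defaults

| parameter | prior | default | notes |
|---|---|---|---|
| $\alpha_\cdot$, $\beta_\cdot$ | $N(0, 10^2)$ | — | weakly informative on log/logit scales |
| $\sigma_b, \sigma_g, \sigma_f, \sigma_\psi$ | PC: $\sigma \sim \mathrm{Exp}(\lambda)$ | $P(\sigma > 1) = 0.01$ | `pc_u`, `pc_alpha` |
| $\phi$ (BYM2 mixing) | PC prior on distance from $\phi = 0$ | $P(\phi < 0.5) = 0.5$ | graph-dependent lookup table |
| $\log \delta_s, \log \delta_t, \log \delta_{st}$ | $N(0, 0.5^2)$ | centred at no rescaling | see below |

**Why the sharing prior is tighter than $N(0,1)$.** A freely scaled shared
*cell-level* field creates a near-flat ridge in the posterior: as
$\delta_{st} \to$ large with $\alpha_b$ drifting, the gate degenerates into
a hard threshold on $\psi_{it}$ that classifies zero against non-zero cells
at essentially unchanged likelihood. Chains that wander onto this ridge mix
arbitrarily slowly and report meaningless sharing coefficients. A
$N(0, 0.5^2)$ prior on $\log\delta$ still covers $\delta \in [0.37, 2.7]$
at $\pm 2$ sd — a generous range for a rescaling coefficient — while making
the degenerate regime improbable. Empirically this moved the worst split-
$\hat R$ in a standard fit from $\approx 2.8$ to $\approx 1.03$. The prior
sd remains a `hp_model_spec()` argument for sensitivity analysis.

The occurrence component is a Bernoulli on the at-least-one-event indicator;
the offset is deliberately excluded from it (flagged as a sensitivity
option, not a default), since the gate models where events occur at all,
not how many.

# Inference

`run_mcmc()` is a blocked adaptive Metropolis-within-Gibbs sampler written
in C++: block random-walk proposals for each component's
intercept-plus-coefficients (target acceptance 0.23), single-site proposals
for every latent field value (target 0.44), and log-scale random walks for
standard deviations, the mixing weight and the sharing coefficients. Step
sizes adapt in batches of 50 during warmup (Robbins–Monro style) and are
frozen afterwards. Constraints are enforced by recentring $u$ (per
component) and $\gamma$ within each sweep.

Two families of *reparameterisation moves* deal with the posterior's ridge
geometry, both plain symmetric Metropolis steps on the state:

* location moves shift $\alpha_p$ against the mean of an uncentred field
  (with $\alpha_b$ co-shifted through the sharing coefficient), leaving both
  linear predictors — hence the likelihood — exactly invariant;
* scale swaps move along the $(\sigma, \delta)$ anti-diagonal, leaving the
  occurrence predictor invariant.

Without these, the intercepts and the $(\sigma_\psi, \delta_{st})$ pair mix
an order of magnitude more slowly.

Chains are initialised at moment-matching values (crude log-SMR intercepts)
with overdispersed jitter, and chain $c$ uses seed `seed + c - 1`; the
entire fit is a pure function of its inputs. Convergence is monitored by
split-$\hat R$ and effective sample size (Geyer initial-positive-sequence)
over the fixed effects, hyperparameters and leading latent values, with an
overall pass rule of $\hat R < 1.05$ — a convention of this package, chosen
because the reporting quantities are medians and tail quantiles.

## Numerical choices

* ZTP sampling uses exact inverse-cdf restriction
  (`qpois(p0 + u(1 - p0))`), valid down to $\mu \to 0$.
* $\log(1 - e^{-\mu})$ and $\log(1 + e^{\eta})$ use `expm1`/softplus guards;
  proposals that overflow the likelihood are rejected rather than crashing,
  and an overflowing *initial* state aborts with a diagnostic.
* Intrinsic log-densities use rank-adjusted generalised log-determinants
  computed by dense eigendecomposition (graphs of the sizes this package
  targets make this cheap); the BYM2 $\phi$ PC prior is precomputed on a
  201-point grid and interpolated linearly.
* All ratio-scale summaries (RR medians, credible intervals, contrasts,
  per-SD percent changes) compute type-7 quantiles on the log/coefficient
  scale and transform, so quantiles commute with the monotone transform.
* Ties in the percentile profile ranking are broken by stable unit order;
  bin sizes differ by at most one.

# The synthetic-data generator

`simulate_dataset()` mirrors the model's own generative process on a
configurable rook lattice: stratum populations uniform in `pop_range`
(default 300–1000 per stratum, 8 age bands $\times$ 2 sexes, i.e. areas of
roughly 5,000–15,000 people), stratum baseline rates with a realistic
age-sex gradient averaging about $10^{-4}$ per person-year
(`default_baseline_rates()`), covariates from a proper CAR field
(`spatial_corr = 0.9` by default, emulating smooth deprivation-like
scores), and counts from the hurdle model at a ground-truth parameter state
(`random_params()`: $\sigma_b = 0.3$, $\phi = 0.6$, $\sigma_g = 0.1$,
$\sigma_f = 0.05$, $\sigma_\psi = 0.1$, $\beta_p = (0.18, -0.08, 0, \dots)$,
$\delta = 1$). Simulated totals are allocated to strata by a multinomial
draw proportional to stratum expected deaths, which keeps indirect
standardisation of the simulated panel self-consistent. The generator
returns the exact RR surface implied by the parameters, so every downstream
summary can be checked against truth.

What it does *not* emulate: realistic population pyramids or their temporal
drift, time-varying covariates, irregular administrative adjacency,
reporting artefacts, or covariate measurement error. Tests passing on this
generator therefore demonstrate internal correctness of the machinery, not
robustness to those features of real data.

## Design choices made where the design was open

* **Reference rates** pool over all areas *and years*, treating age-sex
  rates as constant over the study period — the standard internal indirect
  standardisation, which conserves totals exactly and is what the offset
  formulation assumes.
* **Zero-expected-count cells** are rejected at validation rather than
  dropped: silently dropping cells would corrupt the space-time index grid.
* **Regional RR trends** are computed by aggregating area-year RR draws with
  expected-count weights (not by a separate regional model), respecting the
  population structure of each region.
* **Percentile profiles** rank units by the posterior *median* RR.
* **Exceedance** uses the strict inequality $P(RR > 1)$, banded
  low $[0, 0.2]$, medium $(0.2, 0.8]$, high $(0.8, 1]$, boundary-inclusive
  on the right.
* **Variance decomposition** divides each component's empirical variance
  across all (area, year) units by the variance of the total non-offset,
  non-intercept predictor, per draw; shares need not sum to 100% because
  components may covary.

# Problem sizes and what the tests demonstrate

The package's own validation uses: exact small-graph oracles (dense
pseudo-inverses, brute-force adjacency enumeration, truncated-sum pmf
normalisation); an optimizer oracle on a 500-cell fixed-effects model (the
sampler's posterior mean of each $\beta_p$ against BFGS on the identical
objective, within Monte-Carlo error); prior-only runs against quadrature
moments of the PC priors; reduced simulation-based calibration (100
replicates of a fixed-effects-plus-spatial model on a 6 × 6 lattice, rank
uniformity by $\chi^2$ at the 1% level); and a 20-replicate recovery study
at 100 areas × 10 years with $\beta_p = (0.18, -0.08, 0, \dots, 0)$, where
the 95% CrIs must cover each true coefficient in at least 17 of 20
replicates and the per-SD percent change of the first covariate must
average within ±5 points of $100(e^{0.18} - 1) \approx 19.7\%$.

The recovery study uses spatially *uncorrelated* covariates. This is
deliberate: with strongly autocorrelated covariates the flexible spatial
field can absorb covariate signal (spatial confounding), displacing
coefficient posteriors for reasons unrelated to inference correctness.
That regime is a genuine, documented limitation of this model class — as in
any disease-mapping analysis, covariate effects in the presence of a smooth
confounding field should be interpreted cautiously — and a recovery
benchmark is only meaningful where the coefficients are identifiable.

# Known limitations

* Single-site Metropolis updates keep per-iteration cost linear but limit
  effective sample size per iteration on large graphs; the package targets
  desk-scale problems (up to a few thousand area-years in minutes).
* The sharing construction is scalar per field; component-specific random
  effects (beyond scaling) are out of scope.
* Only Type I (exchangeable) space-time interaction is implemented.
* Spatial confounding between smooth covariates and the BYM2 field is not
  corrected (no restricted spatial regression); see above.

# A worked call

```{r, eval = FALSE}
library(hpmap)
cfg <- write_demo_dataset("demo", n_rows = 6, n_cols = 6, n_years = 8,
                          seed = 1, chains = 2, iters = 2000, warmup = 1000)
res <- run_pipeline(cfg)
read.csv(file.path(res$out_dir, "covariate_effects.csv"))
```

The README shows this pipeline with the numbers it actually printed.
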