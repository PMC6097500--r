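---
title: "Two-scale analysis of lek counts and population dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale analysis of lek counts and population dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Male sage-grouse aggregate each spring on traditional display grounds
(leks); peak male counts there are the standard abundance index for the
species. Oil-and-gas development leaves well pads on the landscape, and a
large literature documents declines in lek attendance with increasing pad
density near a lek. What those local gradients imply for whole populations
(management units) is a separate question: weak density dependence can turn
a small annual effect into a large change in the long-run abundance level,
and regional climate — indexed here by the Pacific Decadal Oscillation
(PDO) — drives inter-decadal fluctuations that can mask or mimic
development effects.

`lekdyn` implements both scales of analysis on a common data-preparation
backbone and propagates fitted effects into population-level impact
estimates, with a synthetic-data generator so the entire chain is testable
without any restricted data.

## The local (lek count) model

The collapsed count of males at lek $i$ in year $y$ is modelled as

$$M_{i,y} \sim \mathrm{NegBin}(\mu_{i,y}, \phi), \qquad
\log \mu_{i,y} = \beta_0 + \beta_A \mathrm{AREA}_{i,y} +
\beta_P \mathrm{PDO}_y + \alpha_{L,i} + \alpha_{Y,y},$$

with crossed random effects $\alpha_L \sim N(0, \sigma_L)$ per lek and
$\alpha_Y \sim N(0, \sigma_Y)$ per year, and the overdispersion
parameterized through the mean-variance relation
$\mathrm{Var}(M) = \mu + \phi\mu^2$ ($\phi = 0$ is the Poisson limit).
AREA is the proportion of a circular buffer around the lek covered by
60 m-radius well-pad discs, lagged one to four years; PDO is the annual
(calendar-mean) index, also lagged. Both covariates are standardized
(sample SD, $n-1$) over the analysis rows, so a coefficient is the
log-scale effect of a one-SD increase and `effect_size()` =
$100(e^\beta - 1)$ is the percent change per SD.

### Marginal likelihood

The random effects are integrated out with a Laplace approximation at
their joint conditional mode. Because the design has at most one
observation per lek-year, the joint precision has an arrow structure
(diagonal lek block, diagonal year block, dense lek-by-year coupling) and
the Newton step and log-determinant are computed with a dense Schur
complement on the smaller year block — no sparse-matrix library is
needed and a full fit at 300 leks by 32 years takes seconds. Variance
parameters are optimized on the log scale with an unconstrained
quasi-Newton method; an SD of exactly zero drops its block from the
integral, and with both SDs zero the marginal likelihood is the exact sum
of negative-binomial log-masses (this identity is tested).

The accuracy of the approximation is characterized, not assumed: against
an adaptive tensor-product Gauss-Hermite oracle on a 3-lek by 3-year toy
the error is below $10^{-4}$ at moderate counts and modest SDs
($\sigma \approx 0.1$) and grows roughly like $\sigma^4$ to about
$10^{-2}$ at field-typical SDs ($\sigma \approx 0.3$). The error shrinks
with the information per effect, i.e. with the number of leks and years;
it is a property of the device itself (the production engines used for
this class of model rely on the same approximation), and at analysis
scale it is far below the ~2-unit AICc resolution that model ranking
relies on.

### Observation-scale R²

Marginal and conditional $R^2$ are computed as a variance decomposition on
the response scale: with $F = e^{X\beta}$ varying over the analysis rows
and $R = e^{\alpha_L + \alpha_Y}$ lognormal, the total variance is
$\mathrm{Var}(FR) + E[\mu + \phi\mu^2]$, the marginal numerator is
$\mathrm{Var}(F)\,E[R]^2$ and the conditional numerator is
$\mathrm{Var}(FR)$. The distribution-specific term is exactly the
mean-variance relation above; the decomposition is validated against a
Monte-Carlo simulation of the fitted model.

## The population (Gompertz) model

Group densities $M_{g,y}$ (mean males per lek over the leks counted in
working group $g$) follow a density-dependent log-linear map:

$$\log M_{g,y} \sim N(\log \mu_{g,y}, \sigma_{\eta,g,y}), \qquad
\log \mu_{g,y} = \beta_0 + (\beta_D + 1 + \alpha_{G,g}) \log M_{g,y-1} +
\beta_A \mathrm{AREA}_{g,y} + \beta_P \mathrm{PDO}_y + \alpha_{Y,y},$$

with the process-error SD depending on survey coverage,
$\log \sigma_{\eta,g,y} = \beta_N + \beta_L \log \mathrm{LEKS}_{g,y}$.
Observer error is fixed at exactly zero (no observation equation): with
both error terms free the pair is not reliably estimable from series of
this length, and ignoring process error instead biases AICc toward
accepting covariates. $\beta_D \in (-2, 0)$ gives stable dynamics
($-1$ is full compensation); the group effect acts on the
density-dependence slope, exactly as the map is written, so groups differ
in their equilibrium rather than their intercept. Rows are year-to-year
transitions; a gap in a group's series breaks the chain (the map is a
one-year transition density and no multi-year variance is defined), and
the first observed year is only a conditioning value.

Conditional on the fixed parameters the model is *linear*-Gaussian in both
random-effect vectors, so the same mode-based marginalization used for the
local model is an exact Gaussian integral here — verified in the tests
against the closed-form marginal covariance
$Z D Z^\top + \mathrm{diag}(\sigma_\eta^2)$.

The carrying capacity

$$\log N_\infty = \frac{-(\beta_0 + \beta_A \mathrm{AREA} +
\beta_P \mathrm{PDO})}{\beta_D + \alpha_G}$$

is the fixed point of the map. It is also where the two scales reconcile:
the log change in $N_\infty$ per unit of covariate is
$-\beta_A / (\beta_D + \alpha_G)$, so with weak density dependence
($|\beta_D| \approx 0.4$) a small annual effect is amplified roughly
2.5-fold in the long-run level. That is why a covariate can carry little
Akaike weight in the transition model and still imply a population-level
impact consistent with summing the local declines.

## Scale and lag selection

Sixty-four local models (four buffer radii 0.8/1.6/3.2/6.4 km, crossed
with independent 1-4-year lags in AREA and PDO) are fitted by maximum
likelihood and weighted by AICc,
$-2\ell + 2k + 2k(k+1)/(n-k-1)$, with $k$ counting every estimated
parameter and $n$ the number of likelihood terms. All members of a scan
are fitted on the identical response rows — those available under the
maximum lag — otherwise AICc values would not be comparable (the common-data
rule). The importance of a radius or lag is its summed Akaike weight. The
population scan fixes the radius at the locally selected scale and crosses
the lags (16 models). For the selected specification the full model and
its three reduced variants {both, AREA only, PDO only, neither} give
predictor weights (summed weight of the two members containing the
predictor) and model-averaged effects: coefficients averaged with zero
substituted where absent, unconditional variance by the standard
model-averaging formula $[\sum_m w_m \sqrt{v_m + (b_m - \bar b)^2}]^2$.
Full-family zero-substitution averaging (not natural averaging) is used
because it matches the weight-averaging convention the analysis mirrors.
Ties in weights are reported as they fall, never silently broken.

## Bayesian engine

The final models are refitted with Normal(0, 5) priors on all betas and on
$\log \sigma$ and $\log \phi$ (uninformative on the scale each parameter
lives on). Because the marginalized posteriors are low-dimensional and
near-Gaussian, the primary kernel is Metropolis-Hastings with an
independence proposal — a multivariate-t matched to the posterior by
pilot chains, mixed with a minority of random-walk steps and a wide
heavy-tailed component so no single high-importance-weight state can trap
the chain: three chains, second halves retained, with the fit failing
loudly unless $\widehat R \le 1.01$ and the effective sample size is
$\ge 1000$ for every structural parameter. The convergence rules are the
substantive contract; the draw budget is not. A gradient-based sampler
reaches ESS $\ge 1000$ from 1,500 retained draws, but these kernels
deliver well under one effective draw per retained draw, so the default
is 2,400 iterations per chain (3,600 retained); on a failed check the
budget doubles, and from the third attempt the sampler switches to
univariate slice sampling in the whitened (curvature-rotated) basis,
which handles the long flat tails of weakly identified log-SD parameters
that defeat both independence and random-walk proposals. Five attempts
are allowed before the fit fails loudly; worlds with very few working
groups leave the group-effect SD so weakly identified that this
correctly ends in an error rather than a certified posterior. Scans are
ML-only for
computational reasons; the Bayesian engine is reserved for the selected
models, whose posterior draws provide the credible intervals on effect
sizes, carrying capacities and impacts.

## Impacts

The local-basis impact for a working group is the percent difference in
the summed expected counts across its leks under observed disturbance
versus none. "None" means raw AREA = 0 mapped through the *fitted*
standardization constants (a standardized zero is not a zero
disturbance). Each lek enters with its own conditional-mode effect so that
big leks dominate the sum (an option treats leks as exchangeable); common
annual and climatic multipliers cancel in the ratio. The population-basis
impact is the percent change in $N_\infty$,
$100(e^{-\beta_A \Delta A/(\beta_D+\alpha_G)} - 1)$. For a single lek the
local-basis impact reduces exactly to the lek-level effect size evaluated
at that lek's disturbance — the consistency identity tying the two effect
pathways together.

## The sensitivity suite

The final population fit is rerun under every combination of the collapse
statistic (rounded mean versus maximum of repeated counts) and the start
year (1985, 1997, 2005). Each variant standardizes its covariates over its
own rows, so its standardized effect is rescaled onto the reference
variant's predictor scale by $\mathrm{SD}_{ref}/\mathrm{SD}_{var}$ before
comparison (the factor is reported). A variant with too few rows to fit is
reported as failed and the suite continues.

## The synthetic world

The generator's defaults state the world the analysis assumes rather than
tuning it: a typical lek of about 10 males ($\beta_0 = \log 10$); a
stationary AR(1) climate index with marginal SD 0.8 (matching the observed
index SDs of 0.82-0.86) and lag-1 autocorrelation 0.5 (decadal
persistence); right-skewed development with gamma-distributed per-lek pad
budgets (shape 0.4-0.5: most leks undeveloped, a few heavily built out),
pads arriving in bursts within 3 km of their lek from a uniform start
year; weak density dependence $\beta_D = -0.38$ (back-solved from the
worked example in which a group at half its carrying capacity of 20
recovers to 13 the next year); group carrying capacities spread
log-uniformly over 13-35 males per lek; and a raw-scale disturbance effect
calibrated so 3% areal disturbance at 3.2 km (lag 1) halves a lek's
expected count — which forces the 6% decline to be exactly 75%, the
log-linear consistency the acceptance suite checks.

`make_fixture()` writes a complete toy study in the raw input formats,
with repeat visits inside the spring window so the filtering and
collapsing rules are exercised, and a JSON manifest of every true
parameter. Counts are generated by a two-layer model (group Gompertz
baseline, lek-level scatter and disturbance response), so both analysis
scales have a recoverable signal. What the generator does *not* emulate:
spatially clustered lek placement, observer-varying detection, demographic
age structure, missing-at-random survey gaps at realistic rates, and
raw-data pathologies (duplicate records, coordinate errors). A green test
therefore establishes correctness of the estimators on the assumed data
model, not robustness to everything field data can do.

## Numerical and design choices

- **Rounding** of the mean of repeated counts is half-to-even, matching
  the default rounding of the computing environment the analysis mirrors.
- **PDO annualization** is the calendar-year mean of the twelve monthly
  values (a seasonal subset is not stated anywhere authoritative);
  incomplete years are flagged. The monthly-to-annual mapping is
  configurable at the data layer.
- **Buffer geometry**: centre-in-circle pad inclusion, whole-pad area,
  overlaps double-counted, proportion capped at 1; pads persist from their
  spud year onward (no reclamation). Inputs must already be in planar
  metres; the package does no reprojection.
- **Zero-male lek-years** count toward "leks counted" in a group-year
  (a surveyed empty lek is information about density).
- **AICc $n$** is the number of likelihood terms: lek-years locally,
  transitions in the population model.
- **Year effects** in the local model are global (shared across working
  groups), as the single $\alpha_Y$ term implies.
- **Default radii** are 0.8/1.6/3.2/6.4 km (the 12.8 km value that
  appears once in a table caption is treated as a typo; the set is
  configurable).
- **Degenerate inputs**: zero-variance predictors error by name;
  zero-density conditioning years are excluded with a warning (their log
  is undefined); malformed dates are rejected record-by-record and
  reported, never silently dropped; $\beta_D + \alpha_G = 0$ has no finite
  carrying capacity and errors.
- **Reproducibility**: every generator and the pipeline thread a single
  integer seed; identical config plus seed gives byte-identical outputs.

## Known limitations

- The Laplace error quantified above means log-likelihoods at very small
  study sizes are approximate; ranking and estimation at analysis scale
  are unaffected, but do not use this engine for n-of-10 datasets where
  exact mixed-model tools are feasible.
- The independence MH sampler relies on the marginalized posterior being
  near-Gaussian; a strongly multimodal posterior would fail the
  convergence rules (loudly) rather than sample it.
- ML intervals are Wald intervals on the transformed scale; at small
  sizes they under-cover slightly (measured ~92-93% at 60 leks by 20
  years against a nominal 95%).
- The local and population models are fitted independently; no joint
  uncertainty propagation between scales is attempted, matching the
  analysis the package mirrors.
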