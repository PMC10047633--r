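---
title: "Hurdle log-normal mixed models for repeated behavioural assays"
author: "hurdlemm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurdle log-normal mixed models for repeated behavioural assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Repeated behavioural assays of the same individuals across several
ecological contexts let us split phenotypic variance into an
*among-individual* component (consistent differences between individuals,
"personality") and a *within-individual* component (residual flexibility),
and to ask whether a rearing treatment -- here, developing alone, with a
conspecific competitor, or with a heterospecific competitor -- reshapes
either component.  The summary statistic of interest is the adjusted
repeatability

$$R = \frac{V_{\mathrm{among}}}{V_{\mathrm{among}} + V_{\mathrm{within}}},$$

computed separately for each treatment and context, together with
treatment contrasts and the among-individual cross-context correlation
matrix (the behavioural-syndrome structure).

The response is the total distance swum in a trial (pixels from video
tracking).  In the familiar (home-tank) context every trial yields a
positive distance.  In the novel-arena and predator-cue contexts many
individuals never leave the covered acclimation zone (AZ) and the trial
records an exact zero.  Distances are therefore modelled with a hurdle
log-normal response in those contexts: a Bernoulli process decides
whether the animal leaves the AZ, and, conditional on leaving, a
log-normal process generates the distance.

## The behavioural model

Let $y_{ick}$ be the distance for individual $i$ (treatment $t(i)$,
egg mass $e(i)$) in context $c \in \{\text{familiar}, \text{novel},
\text{predator}\}$ at trial $k \in \{0, \dots, 5\}$.  For positive
distances,

$$\log y_{ick} \sim \mathcal N\!\left(\mu_{t(i),c} + \beta^{\mathrm{trial}}_c k
 + \beta^{\mathrm{svl}}_c z_{ik} + u_{ic} + w_{e(i),c},\; \sigma^2_{t(i),c}\right),$$

where $z_{ik}$ is the snout--vent length standardised over the whole
dataset.  In the novel and predator contexts an observation is an exact
zero with probability $p_{t,c} = \operatorname{logit}^{-1}(h_{t,c})$,
independent of the continuous part (the standard hurdle factorisation:
zeros contribute only the hurdle mass, and carry no information about
the latent effects).  The hurdle submodel is intercept-only by treatment.

The random effects are the core of the model:

* $\mathbf u_i = (u_{i1}, u_{i2}, u_{i3})^\top \sim \mathcal N_3(\mathbf 0,
  \Sigma_{t(i)})$ with $\Sigma_t = D_t \Omega_t D_t$, $D_t =
  \operatorname{diag}(\mathrm{sd}^{\mathrm{among}}_{t,c})$: each treatment
  has its own among-individual SDs *and* its own $3\times 3$ cross-context
  correlation matrix $\Omega_t$.  Individuals experience exactly one
  treatment, so the three blocks are disjoint.
* $w_{ec} \sim \mathcal N(0, V^{\mathrm{egg}}_c)$: egg-mass (clutch)
  intercepts, independent across contexts -- a single egg-mass variance
  per context, with no cross-context egg-mass correlation.
* residual SDs $\sigma_{t,c}$ are treatment-by-context constants -- a
  distributional (double-hierarchical) submodel that lets the treatment
  act on the *within*-individual variance, not just the mean.

Priors are weakly informative and configurable via `behavior_spec()`:
$\mathcal N(0, 10^2)$ on every fixed effect and hurdle intercept,
half-Student-t$(3, 2.5)$ on every SD, and LKJ$(2)$ on every correlation
matrix.  These are the conventional defaults for this model class; the
data here (hundreds of trials per cell) dominate them for all
population-level parameters.

## The body-size model

Growth is modelled separately: a Gaussian random-slope model for the six
per-trial SVL measurements,

$$\mathrm{svl}_{ik} \sim \mathcal N\!\left(\alpha_{t(i)} + \beta k + g_{0i}
 + g_{1i} k + w_{e(i)},\; \sigma^2\right),$$

with per-treatment $2 \times 2$ covariance for $(g_{0i}, g_{1i})$
(variance in initial size, variance in growth rate, and their
correlation), an egg-mass intercept and a common residual.  SVL then
enters the behavioural model as an observed covariate; the two models
are fitted independently.

## Posterior computation

`fit_behavior()` and `fit_bodysize()` run a blocked MCMC scheme written
for exactly this model family:

* **Gaussian blocks are conjugate.**  Fixed effects and egg-mass
  intercepts are drawn jointly from their multivariate normal
  conditional (folding the egg intercepts into the same block removes
  the strong posterior correlation between population means and clutch
  effects that only eight clutches induce).  Each individual's 3-vector
  (or (intercept, slope) pair) is drawn from its exact trivariate
  (bivariate) normal conditional.
* **Variances with half-t priors are conjugate too**, through the
  inverse-gamma scale-mixture representation of the half-t, so residual
  and egg-mass variances need no tuning.
* **SD/correlation blocks use componentwise adaptive random-walk
  Metropolis** on $(\log \mathrm{sd}, \text{correlations})$, with the
  LKJ density as prior and proposals outside the positive-definite cone
  rejected.  Proposal scales adapt toward 44% acceptance during burn-in
  only, so the retained draws come from a fixed kernel.
* **Interweaving.**  A centred update of $(\mathrm{sd}, \Omega)$ given
  $u$ mixes poorly when among-individual variance is small (the funnel),
  and the population means mix poorly when traded against the mean of
  $u$.  Each iteration therefore also (i) re-updates the SD/correlation
  block in the *non-centred* parameterisation, holding the whitened
  effects $\tilde{\mathbf u}_i = A_t^{-1}\mathbf u_i$ fixed
  ($A_t A_t^\top = \Sigma_t$), and (ii) redraws each treatment's means
  from their conditional with $\mu + u$ held fixed.  Both are exact
  Gibbs/Metropolis moves on reparameterised coordinates; together they
  remove the dominant sources of autocorrelation that a purely centred
  scheme exhibits on this model (check `diagnostics()` on any fit).
* Hurdle intercepts have a Bernoulli likelihood that depends on the data
  only through the zero counts; they get their own adaptive random-walk
  step.  Cells with no observations fall back to exact prior draws, so
  prior-only sampling (`fit_behavior(NULL, ...)`) reproduces the priors.

The report-scale default (`mcmc_control()`) is four chains of 8500
iterations, burn-in 1000 and thinning 100, retaining $4 \times 75 = 300$
draws.  `mcmc_control_test()` (2 chains of 500, burn-in 100, thin 2) is
the desk-scale setting used throughout the test suite; it keeps a full
fit of the complete design (2898 records) to seconds rather than
minutes on one CPU.
Chains run sequentially from seeds derived from the master seed, so every
fit is exactly reproducible.  Convergence is summarised by split R-hat
and effective sample size computed in-package with the standard
split-chain definitions; any R-hat above 1.05 raises a flag that
`print()`, `summary()` and the pipeline log all surface.

## Derived statistics

All reported quantities are computed per retained draw, then summarised
by the posterior mean and (by default) the 95% highest-posterior-density
interval; equal-tail quantile intervals are available everywhere via
`type = "quantile"`, since reports in this literature label intervals
either way:

* group-effect SDs are squared to variances (`sd_to_variance()`);
* the log-scale residual variance is exponentiated to the natural-scale
  within-individual variance (`within_variance_natural()`).  This simple
  exponential is the reporting convention this package mirrors; it is
  *not* the complete log-normal data-scale variance
  $(e^{\sigma^2}-1)e^{2\mu+\sigma^2}$, which is available behind the
  `complete = TRUE` flag but off by default;
* repeatability is the per-draw ratio $V_a/(V_a+V_w)$.  Averaging the
  ratio rather than taking the ratio of averages leaves a small Jensen
  gap (of order 0.001--0.005 here) between the posterior-mean
  repeatability and the value implied by the posterior-mean variances;
* hurdle intercepts are inverse-logit transformed
  (`logit_to_probability()`);
* the per-draw among-individual covariance matrix is rebuilt from the SD
  and correlation draws and converted to a correlation matrix by
  diagonal normalisation (`cov_to_corr()`), per draw;
* treatment contrasts are per-draw differences, summarised both signed
  (direction) and in absolute value.  The absolute-value summary mirrors
  the reporting convention of variance-contrast tables in this
  literature (whose intervals are bounded below by zero); the signed
  summary is what you want for directional claims.  Both are always
  produced and labelled.

## The synthetic-data generator

`simulate_trials()` reproduces the repeated-measures design the models
assume, with known truth retained for recovery testing.  The defaults in
`default_params()` *are* the study conditions the package emulates: 54,
56 and 51 focal individuals in the no-competition, conspecific and
heterospecific treatments; 6 trials in each of 3 contexts (2898
records); 8 egg masses spanning treatments (two nests per batch over
four batches); population means, slopes, variances and AZ probabilities
set to the posterior means of the fitted models that motivated the
package.  Where no published value exists the defaults are fixed once at
realistic values: body-size residual variance 0.04 mm² (SD 0.2 mm,
consistent with 0.1 mm measurement resolution), zero intercept--slope
correlation in growth, and identity cross-context correlation matrices
(the motivating analysis found no behavioural syndrome).  Optional
missing-at-random record dropout (off by default) emulates the deaths
and recording failures such experiments report.

What the generator does *not* emulate: tracking noise and video
artefacts, context order and carry-over effects, non-random mortality,
and any dependence of the zero process on the individual (the hurdle is
intercept-only, matching the model).  Passing recovery tests therefore
demonstrates that the estimator recovers the parameters of its own data
model at the study's design size -- not that the data model is true of
any real tadpole.

## Numerical and design choices

* Zeros in the familiar context are rejected at validation: the familiar
  response is plain log-normal, and a zero there would have likelihood
  zero.  Catching it at the door gives a named error instead of `-Inf`.
* SVL is standardised globally (one mean and SD over all records), not
  within treatment; with growth differing by treatment the two choices
  differ, and the global convention matches "scaled body size" entering
  one multivariate model.
* Degenerate latent covariances (an SD of exactly zero) are handled as
  point masses in the likelihood functions, so nested models (e.g. zero
  slope variance) evaluate finitely.
* HPDI is the exact shortest window over the sorted draws containing
  `ceiling(mass * n)` of them; ties resolve to the left-most window.
* Coverage in `recovery_experiment()` uses central (equal-tail)
  intervals, which are invariant to the monotone reporting transforms
  (square, exp, inverse-logit) -- HPD intervals are not.
* Test-suite problem sizes: the recovery experiment in the acceptance
  tests fits the full design (2898 records) once, plus 20 replicates at
  half the design size for coverage and rank checks; property tests use
  8--30 individuals per treatment.  These sizes are the package's choice
  of desk-scale experiment, balancing Monte-Carlo resolution against a
  test suite that runs in minutes.  Note that the top two generating
  repeatabilities differ by only 0.03, so the ranking of the largest
  posterior-mean repeatability across cells is genuinely noisy at these
  sample sizes -- an honest property of the design, which the recovery
  report quantifies rather than hides.

## Limitations

* The sampler is specific to this model family; it is not a generic
  GLMM engine.  Its Metropolis blocks would need retuning for designs
  with many more contexts.
* At desk-scale settings, near-zero variance components keep modest
  effective sample sizes (tens); report-scale settings or longer chains
  are advised for publication-grade interval endpoints on those
  parameters.
* The hurdle and continuous processes are independent by construction;
  if leaving the AZ and distance swum share individual-level causes,
  that correlation is invisible to this model.
* With eight egg masses the clutch variance is weakly identified and its
  posterior leans on the half-t prior's scale -- the same caveat applies
  to the motivating analysis.
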