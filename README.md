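# hurdlemm

Bayesian hurdle log-normal mixed models for repeated behavioural
measures, with treatment-specific variance partitioning, adjusted
repeatability and behavioural-syndrome correlations.

## The problem this package addresses

Developmental experiments in behavioural ecology repeatedly assay the
same individuals across several ecological contexts — here, tadpoles
reared alone, with a conspecific competitor, or with a heterospecific
competitor, each assayed 6 times in a familiar home tank, a novel arena
and a predator-cue arena.  The questions are about *variance*, not just
means: does competition change the variance **among** individuals
(consistent personality differences), the variance **within**
individuals (behavioural flexibility), and hence the adjusted
repeatability

R = V_among / (V_among + V_within),

estimated per treatment × context, together with treatment contrasts and
the 3×3 among-individual cross-context correlation matrix per treatment
(the behavioural syndrome)?

The response — total distance swum, in pixels — is positive in the
familiar context but contains exact zeros in the novel and predator
contexts (animals that never left the covered acclimation zone, AZ).
The package therefore fits a multivariate **hurdle log-normal** mixed
model: a Bernoulli hurdle with treatment-specific logit intercepts for
the zeros, and a log-normal mixed model for positive distances with

* fixed effects: mean log-distance per treatment × context, a trial
  slope and a standardised-body-size (SVL) slope per context;
* random effects: per-individual 3-vectors across contexts with
  treatment-specific SDs **and** treatment-specific 3×3 correlation
  matrices (LKJ prior), plus egg-mass (clutch) intercepts per context;
* a distributional residual submodel: treatment × context residual SDs,
  so treatments can act on within-individual variance directly.

A companion Gaussian random-slope model handles the repeated body-size
measurements (variance in initial size and in growth rate per
treatment).  Priors: Normal(0, 10) on fixed effects, half-Student-t(3,
2.5) on SDs, LKJ(2) on correlations.  Sampling is by a blocked
Gibbs/Metropolis scheme with interweaving (details and design rationale
in `vignettes/hurdle-lognormal-repeatability.Rmd`).

A first-class synthetic-data generator (`simulate_trials()`) reproduces
the study design — 54/56/51 focal individuals across the three
treatments, 6 trials × 3 contexts, 8 egg masses, anchored population
parameters — so the entire analysis is testable against known truth.

## Worked example

```r
library(hurdlemm)

sim <- simulate_trials(default_params(seed = 42))
sim
#> Simulated behavioural experiment: 2898 trial records, 161 individuals, 8 egg masses
#>   zero fraction by context: familiar=0.000, novel=0.444, predator=0.455

fit <- fit_behavior(sim$trials, control = mcmc_control_test(seed = 42))
fit
#> Multivariate hurdle log-normal mixed model fit
#>   individuals: 161  egg masses: 8  records: 2898
#>   chains: 2  retained draws: 400  (200 per chain)
#>   WARNING: split R-hat exceeds 1.05 for some parameters -- inspect diagnostics(fit)

repeatability_summary(fit)
#>        treatment  context     R lower upper
#> 1 no_competition familiar 0.097 0.039 0.163
#> 2 no_competition    novel 0.041 0.000 0.111
#> 3 no_competition predator 0.060 0.008 0.126
#> 4    conspecific familiar 0.090 0.040 0.149
#> 5    conspecific    novel 0.211 0.078 0.339
#> 6    conspecific predator 0.124 0.038 0.217
#> 7 heterospecific familiar 0.241 0.150 0.321
#> 8 heterospecific    novel 0.166 0.049 0.277
#> 9 heterospecific predator 0.020 0.000 0.058
```

Each row is the posterior mean and 95% highest-posterior-density
interval of the adjusted repeatability for one treatment × context cell,
computed per retained draw as V_among/(V_among + V_within) with V_among
the squared among-individual SD and V_within the exponential of the
log-scale residual variance.  At this desk-scale setting (2 × 200
retained draws) the fit reproduces the generating structure: activity in
the heterospecific treatment is the most repeatable cell (truth 0.229,
estimate 0.241), and near-zero cells shrink toward zero.  The
convergence warning is the desk-scale settings talking — report-scale
settings (`mcmc_control()`: 4 chains × 8500 iterations, burn-in 1000,
thin 100, 300 retained draws) clear it.

Hurdle intercepts on the probability scale, and a treatment contrast of
repeatability draws:

```r
hurdle_probability(fit)
#>        treatment  context     p lower upper
#> 1 no_competition    novel 0.397 0.342 0.446   # truth 0.375
#> ...

Rd <- attr(repeatability_summary(fit), "draws")
treatment_contrast(list(no_competition = Rd[, "no_competition.familiar"],
                        heterospecific = Rd[, "heterospecific.familiar"]),
                   c("no_competition", "heterospecific"))
#> Contrast no_competition - heterospecific
#>   signed:   -0.144 [-0.262, -0.044]
#>   absolute: 0.144 [0.044, 0.262]
```

The signed summary gives direction; the absolute summary mirrors the
reporting convention of variance-contrast tables (bounded below by 0).

An end-to-end run (simulate or analyse a CSV, fit both models, write
posterior draws, diagnostics and six report tables):

```r
cfg <- pipeline_config(mode = "simulate", outdir = "out", seed = 1,
                       control = mcmc_control_test(seed = 1))
run_pipeline(cfg)
```

`recovery_experiment()` measures bias, RMSE and interval coverage of
every parameter class against known truth across replicate simulations.

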