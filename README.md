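# powerpost

Thermodynamic integration (TI) for Bayesian model evidence, in R.

## The problem

Bayesian model comparison ranks competing models `m` of the same data `y` by
the log model evidence (marginal likelihood)

    ln p(y | m) = ln ∫ p(y | θ, m) p(θ | m) dθ,

the normalizer of Bayes' theorem, which automatically trades model fit against
complexity. For almost every model of interest — notably dynamic causal models
(DCMs) of fMRI effective connectivity, where competing network hypotheses are
compared through their evidence — the integral is intractable, and the popular
shortcuts have known failure modes: variational bounds can be loose or stuck
in local optima, and the simple sampling estimators are systematically biased.

`powerpost` implements the Monte Carlo route that is widely regarded as the
reference method. Writing the *power posterior* at inverse temperature β,

    p_β(θ | y, m) ∝ p(y | θ, m)^β p(θ | m),      β ∈ [0, 1],

the log evidence is the thermodynamic integral of the expected log-likelihood
("accuracy") along the prior → posterior path,

    ln p(y | m) = ∫₀¹ E[ ln p(y | θ, m) ]_{p_β} dβ,

estimated by a **population MCMC** sampler (one Metropolis chain per β on a
fifth-order temperature ladder, with between-chain swap moves) and trapezoidal
quadrature over the per-temperature Monte Carlo means. The biased
prior-arithmetic-mean (AME, biased down) and posterior-harmonic-mean (HME,
biased up) estimators are included as references. Two model families are
built in:

* **Conjugate Bayesian linear regression** with the closed-form evidence —
  the oracle used to benchmark all estimators;
* **A deterministic DCM of fMRI** (bilinear/nonlinear neuronal dynamics plus
  the balloon–windkessel BOLD observation model, integrated in compiled
  code) with an SNR-controlled simulator and five bundled 3-region example
  models for model-recovery studies.

Intended users: anyone who needs trustworthy marginal likelihoods for
moderate-dimension models — and, specifically, neuroimaging methodologists
comparing DCM network hypotheses by sampling rather than variational bounds.

## Worked example

Estimate the evidence of a conjugate linear model, where the truth is known:

```r
library(powerpost)

model <- generate_linreg_dataset(p = 8, M = 100, seed = 42) # ANOVA design
linreg_log_evidence(model)   # analytic: -275.229

fit <- model_evidence(model, n_chains = 16, order = 5,
                      n_samples = 1500, burn_in = 500, seed = 1)
summary(fit)
```

```
Population MCMC: 16 chains (order 5 schedule), 1500 retained sweeps, 500 burn-in, seed 1
Max split-half R-hat of log-likelihood: 1.0159
Within-chain acceptance range: 0.21 - 1.00

Log model evidence for linreg_p8_M100_seed42
  TI     -275.346 nats  (MC-SE 0.151)
  AME    -278.041 nats
  HME    -267.732 nats
```

TI lands within ~0.1 nat of the analytic value −275.229; the arithmetic mean
under-, the harmonic mean over-estimates — the characteristic bias pattern
that worsens with dimension (`run_linreg_benchmark()` maps it out, and
`plot_benchmark()` draws the error-bar figure). The convergence summary is the
maximum over temperatures of the split-half Gelman–Rubin statistic of each
chain's log-likelihood trace; values below 1.1 are read as converged.

The same interface drives DCM model comparison:

```r
specs <- dcm_fixture_models()                    # five 3-region DCMs
dat <- add_noise_at_snr(integrate_dcm(specs$m5), snr = 1, seed = 1)
fits <- lapply(specs[c("m1", "m5")], function(s)
  model_evidence(dcm_model(s, dat$observed), methods = "ti",
                 n_samples = 2000, burn_in = 500, seed = 2))
sapply(fits, function(f) f$estimates$ti$lme)     # m5 wins on m5 data
```

`run_model_recovery()` scales this up to the full confusion-matrix study and
`chi_square_recovery()` compares two methods' hit counts. A thin command-line
front end with `evidence`, `simulate-dcm`, `benchmark-linreg`, `recover-dcm`
and `chi2` subcommands lives at `inst/cli/powerpost.R`.

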