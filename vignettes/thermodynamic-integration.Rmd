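---
title: "Estimating the log model evidence by thermodynamic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the log model evidence by thermodynamic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerpost)
```

## The estimation problem

Bayesian model comparison scores a model $m$ by its log evidence (marginal
likelihood),
$$\ln p(y \mid m) = \ln \int p(y \mid \theta, m)\, p(\theta \mid m)\, d\theta,$$
which trades off fit against complexity but is rarely available in closed
form. `powerpost` estimates it by **thermodynamic integration (TI)**. Define
the *power posterior* at inverse temperature $\beta \in [0, 1]$,
$$p_\beta(\theta \mid y, m) \propto p(y \mid \theta, m)^\beta\, p(\theta \mid m),$$
which interpolates between the prior ($\beta = 0$) and the posterior
($\beta = 1$). Provided the prior is properly normalized, the log evidence is
the integral of the expected log-likelihood along this path:
$$\ln p(y \mid m) = \int_0^1 \mathrm{E}\big[\ln p(y \mid \theta, m)\big]_{p_\beta}\, d\beta.$$
The integrand, the *accuracy* $A(\beta)$, is monotonically increasing in
$\beta$ (its derivative is the variance of the log-likelihood under the power
posterior), and at any $\beta$ the negative free energy decomposes as
$-F_H(\beta) = \beta A(\beta) - KL[p_\beta \,\|\, \text{prior}]$, i.e.
accuracy minus complexity; `decompose_free_energy()` exposes this
decomposition and `accuracy_curve()` the integrand.

In practice the inner expectation at each $\beta_j$ of a fixed schedule is
replaced by the Monte Carlo mean $E_{MC}(\beta_j)$ of the log-likelihood over
draws from $p_{\beta_j}$, and the outer integral by the trapezoid rule
(`ti_estimate()`). The two reference estimators with known biases are also
provided: the prior arithmetic mean (`ame_estimate()`, biased downward — prior
draws rarely hit the high-likelihood region) and the posterior harmonic mean
(`hme_estimate()`, biased upward with potentially infinite variance). Both are
included for benchmarking, not as recommended outputs.

## Sampling: population MCMC

`run_population_mcmc()` runs one random-walk Metropolis chain per temperature.
Neighbouring chains exchange states through Metropolis swap moves (accepted
with probability $\min\{1, \exp[(\beta_i - \beta_j)(\ell_j - \ell_i)]\}$ on
the cached log-likelihoods), which lets information from the posterior end of
the ladder accelerate mixing at the tempered end. Design choices the
literature leaves open, fixed as follows:

* **Temperature schedule.** $\beta_j = (j/(N-1))^{5}$, the fifth-order power
  rule (`power_schedule()`). The accuracy curve of most models rises steepest
  near $\beta = 0$; the fifth-order rule concentrates temperatures there. The
  desk-scale default is $N = 16$ chains; study-scale analyses typically use
  64.
* **Proposals.** Per-chain isotropic Gaussian random walk in per-coordinate
  scaled units. During burn-in a Robbins–Monro update steers a global
  per-chain log step size toward a 25% acceptance rate, and every 100 sweeps
  the per-coordinate scales are re-estimated from the chain's own recent
  draws (diagonal adaptive Metropolis). Adaptation is frozen when burn-in
  ends, so retained samples come from a fixed, valid kernel.
* **The $\beta = 0$ chain** is sampled by independent prior draws — the power
  posterior at $\beta = 0$ *is* the prior, so this is exact.
* **Swap scheme.** One swap pass per sweep, alternating even and odd adjacent
  pairs, so every adjacency is visited every two sweeps.
* **Convergence.** Chains at different temperatures target different
  distributions, so the potential scale reduction factor is computed per
  temperature on split halves of the retained log-likelihood trace
  (`split_rhat()`); the reported summary is the maximum over temperatures,
  read against the conventional 1.1 threshold.
* **Monte Carlo error.** Per-temperature standard errors of $E_{MC}$ use an
  autocorrelation-corrected effective sample size (`ess()`, initial positive
  sequence truncation), not the naive $\sqrt{K}$; they are propagated through
  the trapezoid weights assuming independence across temperatures.
* **Reproducibility.** One master seed drives the whole run through R's RNG
  stream in a fixed canonical update order; identical seeds give bit-identical
  traces.

## Built-in model families

### Conjugate linear regression

`linreg_model()` implements the Gaussian–Gaussian regression
$\theta \sim N(0, \Pi_p^{-1})$, $y \sim N(X\theta, \Pi_e^{-1})$, whose log
evidence and posterior moments are available in closed form
(`linreg_log_evidence()`, `linreg_posterior()`); all determinants and solves
are Cholesky-based, never explicit inverses, so the family is stable up to at
least $p = 32$. `generate_linreg_dataset()` builds the benchmark condition:
a one-way ANOVA block design with $M = 100$ observations, prior variance 16
and noise variance 10, excess rows assigned to the last level, coefficients
drawn from the prior and data from the likelihood (theta draw first, then the
noise draw, so datasets are bit-reproducible). This family is the oracle for
everything else: the benchmark (`run_linreg_benchmark()`) measures each
estimator's error against the analytic evidence as the dimension grows.

### A DCM of fMRI

`dcm_spec()` defines a deterministic dynamic causal model: neuronal dynamics
$$\dot x = \Big(A + \textstyle\sum_j u_j B^{(j)} + \sum_d x_d D^{(d)}\Big) x + C u,$$
(endogenous coupling $A$, bilinear input modulation $B$, driving inputs $C$,
nonlinear gating $D$, all in Hz) feeding the balloon–windkessel haemodynamic
model per region and its BOLD output equation, in percent signal change.
Numerical and modelling choices:

* **Haemodynamic constants** are fixed at the conventional values
  ($\kappa = 0.64\,s^{-1}$, $\gamma = 0.32\,s^{-1}$, $\tau = 2\,s$,
  $\alpha = 0.32$, $\rho = 0.32$, $V_0 = 0.04$; output constants
  $k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$) and are not sampled: fixing
  the observation model isolates inference on connectivity.
* **Self-connections** are parameterized as $-0.5\,e^{a}$ Hz so they are
  always negative (stability), standard DCM practice.
* **Log-scale haemodynamics.** Inflow, volume and deoxyhaemoglobin content
  are integrated as logs, so they stay positive for every connectivity draw;
  log-states are read through a generous $\pm 10$ clamp and the BOLD output
  saturates at $\pm 100$% signal change. Neither guard is reachable from
  trajectories of physiological magnitude (fixture signals stay below ~10%);
  their sole purpose is to keep the likelihood finite and well-scaled for the
  extreme parameter draws that the $\beta \approx 0$ chains must average
  over. Genuine neuronal blow-up (state norm above `state_bound`) is a
  divergence: `integrate_dcm()` raises a classed error and
  `dcm_log_likelihood()` returns $-\infty$, so tempered chains simply reject
  the move.
* **Integrator.** Fixed-step integration at the input resolution with
  `substeps` sub-steps per input bin. The default is Euler with 2 sub-steps
  (an effective 0.25 s step for 2 Hz inputs): at the bundled study
  conditions its discretization error is roughly 3% of the SNR = 1
  measurement noise, and because simulation and inversion share one
  integrator the likelihood is exactly consistent with the generative
  process. A single Euler step per 0.5 s bin is *not* offered as a default
  because the explicit haemodynamic update is unstable at that step for
  modulated fixtures. Classical RK4 at the same step (`method = "rk4"`) is
  essentially converged (halving its step changes the solution by under
  $10^{-3}$ RMS) and is the right choice whenever the forward solution
  itself is the quantity of interest.
* **Priors.** $N(0, 1/16)$ on self, off-diagonal and modulatory parameters;
  $N(0, 1/4)$ on driving-input weights; per-region log noise precision
  $N(\log(1/\widehat{\mathrm{var}}(y_r)), 1)$, centred empirically at the
  data variance. The last two choices are deliberate: the $\beta = 0$ end of
  the thermodynamic integral averages the log-likelihood over *prior* draws,
  so its magnitude is set by the worst prior-predictive mismatch. A noise
  prior centred at a fixed precision makes that magnitude depend on the
  units of the signal, and overly wide driving-input priors inflate it by
  orders of magnitude; both would make the first quadrature cells of a
  16-temperature schedule erratic. Empirical centring applies the same
  transformation of the data to every candidate model, so model comparison
  is unaffected.
* **Noise / SNR.** `add_noise_at_snr()` adds per-region iid Gaussian noise
  with SD equal to the per-region signal SD divided by the target SNR — SNR
  is defined as the ratio of signal standard deviation to noise standard
  deviation.

### The bundled fixtures

`dcm_fixture_models()` returns five 3-region, two-input specifications
spanning the linear/bilinear/nonlinear classes: m1 (driving inputs only, the
null hypothesis), m2 and m3 (bilinear modulation of one of the two forward
connections into region 3), m4 (input u1 modulates region 3's
self-connection) and m5 (activity in region 2 nonlinearly gates the
region 1 → region 3 connection). Acquisition follows the simulated-data
conditions: TR = 2 s, 720 scans, inputs sampled at 2 Hz, SNR = 1. The input
time courses are boxcars (u1: 40 s on/off; u2: 60 s on/off) whose on-phases
overlap in a varying pattern — the variation that makes modulatory effects
identifiable. The numeric connectivity values (self-connections −0.5 Hz,
forward connections 0.4 Hz, driving inputs 0.25 Hz, modulations ±0.6/−0.4 Hz)
are this package's own synthetic fixture values, chosen once in the typical
range of simulated DCM studies so that neuronal excursions stay below about
one and the BOLD response in the low percent range; they are not transcribed
from any external dataset.

## What the experiments show — and what they do not

`run_linreg_benchmark()` reproduces the estimator-accuracy comparison at desk
scale (default: $p \in \{2, 8, 16\}$, 10 repetitions, 16 chains, 1500
retained sweeps; the full-scale study uses $p$ from 2 to 32, 64 chains and
6000 samples). Expected picture: TI errors within a nat across dimensions,
HME above the analytic value, AME below, both degrading with dimension.

`run_model_recovery()` reproduces the model-recovery design: per generating
model, one noiseless series, several noise realizations, every candidate
inverted on every dataset, and the argmax-evidence model counted
(columns = generating model, rows = inverting model; ties count as incorrect
with a warning; failed inversions go to a failures log). The desk-scale
default uses the {m1, m5} pair, 5 datasets each — m5 data are easily
distinguished from m1 (the gating effect is tens of standard errors), while
m1 data test whether TI resolves an Occam gap of order one nat against the
richer nested model. `chi_square_recovery()` compares two methods' correct
counts by a Pearson 2×2 test without continuity correction (only that choice
reproduces the printed benchmark statistic from its integer counts; a zero
marginal returns 0 with a warning by convention).

Because the synthetic data are generated by the package's own forward model,
these experiments validate the *estimators and sampler*, not the biological
realism of the DCM: real fMRI has drifts, physiological noise,
regionally-correlated errors and haemodynamic variability that the generator
deliberately omits (no confound terms, zero-mean baseline, fixed
haemodynamics). Passing tests therefore certify estimator calibration under
the stated conditions, not performance on empirical data.

## Problem sizes and numerical tolerances

The package's own test suite runs everything at desk scale — 16 chains,
1500–2000 retained sweeps, 3 linear-model dimensions × 10 repetitions, a
2-model recovery with 5 datasets per generator — sizes chosen so the whole
suite completes on a single CPU in well under half an hour while leaving the
qualitative structure of the full-scale studies intact. Degenerate inputs are
pinned by exact conventions: trapezoid quadrature is exact for constant and
linear integrands; all three estimators return exactly $c$ for a model with
constant log-likelihood $c$; R-hat of an all-constant trace is 1 by
convention; equal-temperature or equal-state swaps are always accepted;
$0 \cdot (-\infty) = 0$ at $\beta = 0$ so diverged likelihoods never
influence prior-chain acceptance.

## Known limitations

* The trapezoid rule on 16 temperatures carries a small systematic
  discretization bias near $\beta = 0$ for strongly peaked models (the
  full-scale remedy is simply more chains; the bias is shared across
  candidate models compared on the same data).
* AME and HME are implemented faithfully as the known-biased references they
  are; do not report them as evidence estimates.
* The sampler is a random-walk method: posteriors with strong correlations
  or multimodality in more than a few dozen dimensions will mix slowly;
  gradient-based or Riemannian samplers are out of scope.
* Only single-subject, deterministic DCMs for fMRI are implemented — no
  EEG/MEG, layered, stochastic or hierarchical variants, and no variational
  inversion.
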