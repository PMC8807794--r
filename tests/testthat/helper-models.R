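# Shared fixtures, all built in code.

# A model with constant log-likelihood c: every evidence estimator must
# return exactly c on it.
constant_model <- function(c = -3.7, dim = 2L) {
  bayes_model(
    name = sprintf("constant_%g", c), dim = dim,
    log_prior = function(theta) sum(stats::dnorm(theta, log = TRUE)),
    log_likelihood = function(theta) c,
    prior_sampler = function(n) matrix(stats::rnorm(n * dim), n, dim)
  )
}

# Standard-normal prior with flat likelihood: the posterior is the prior.
flat_model <- function(dim = 1L) constant_model(0, dim)

# Hand-built population_trace with a prescribed log-likelihood matrix,
# for exercising the estimators without running the sampler.
synthetic_trace <- function(betas, loglik) {
  loglik <- as.matrix(loglik)
  stopifnot(ncol(loglik) == length(betas))
  K <- nrow(loglik)
  structure(
    list(schedule = structure(list(betas = betas, order = NA_real_),
                              class = "temperature_schedule"),
         draws = rep(list(matrix(0, K, 1)), length(betas)),
         loglik = loglik, logprior = loglik * 0,
         acceptance = list(within = rep(NA_real_, length(betas)),
                           swap = rep(NA_real_, length(betas) - 1L)),
         burn_in = 0L, n_samples = K, seed = NA_integer_,
         model_name = "synthetic", dim = 1L),
    class = "population_trace")
}

# Small DCM specification for structural unit tests (short acquisition so
# integrations cost microseconds; study-scale tests use the full fixtures).
tiny_dcm_specs <- function(n_scans = 60) dcm_fixture_models(n_scans = n_scans)

# Closed-form Gaussian KL divergence KL[N(m1, S1) || N(m0, S0)] given
# precision parameterizations, used as the oracle for the free-energy
# decomposition.
gaussian_kl <- function(mean1, prec1, mean0, prec0) {
  S1 <- solve(prec1)
  d <- length(mean1)
  0.5 * (sum(diag(prec0 %*% S1)) - d +
           drop(t(mean1 - mean0) %*% prec0 %*% (mean1 - mean0)) +
           determinant(prec1)$modulus - determinant(prec0)$modulus)
}
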