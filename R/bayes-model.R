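#' Generic Bayesian model contract
#'
#' A `bayes_model` is the pluggable triple every evidence estimator in this
#' package consumes: a normalized log-prior density, a log-likelihood, and a
#' sampler from the prior. All densities are natural logs (nats). The
#' log-likelihood must return a finite value or `-Inf` for any real parameter
#' vector of length `dim`; it must never return `NA`/`NaN` (a `-Inf` value is
#' how built-in models signal, e.g., a diverged ODE integration, so that
#' tempered chains simply reject the move).
#'
#' @param name identifier for the model (character scalar).
#' @param dim number of free parameters (integer >= 1).
#' @param log_prior function(theta) -> log prior density in nats. Must be a
#'   properly normalized density: thermodynamic integration identifies the
#'   evidence with a free-energy difference only when the prior integrates
#'   to one.
#' @param log_likelihood function(theta) -> log likelihood in nats
#'   (finite or `-Inf`, never `NaN`).
#' @param prior_sampler function(n) -> n x dim matrix of draws from the prior,
#'   consuming the current R RNG stream.
#'
#' @return An object of class `bayes_model`.
#' @export
bayes_model <- function(name, dim, log_prior, log_likelihood, prior_sampler) {
  stopifnot(is.character(name), length(name) == 1L)
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L)
    stop("'dim' must be an integer >= 1", call. = FALSE)
  stopifnot(is.function(log_prior), is.function(log_likelihood),
            is.function(prior_sampler))
  structure(
    list(name = name, dim = dim, log_prior = log_prior,
         log_likelihood = log_likelihood, prior_sampler = prior_sampler),
    class = "bayes_model"
  )
}

#' @export
print.bayes_model <- function(x, ...) {
  cat("<bayes_model>", x$name, "with", x$dim, "free parameter(s)\n")
  invisible(x)
}

# Evaluate log-likelihood defensively: NaN is a contract violation of the
# model, mapped to an error early rather than corrupting a long run.
eval_loglik <- function(model, theta) {
  ll <- model$log_likelihood(theta)
  if (is.nan(ll) || is.na(ll))
    stop("log_likelihood returned NaN/NA; models must return finite or -Inf",
         call. = FALSE)
  ll
}
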