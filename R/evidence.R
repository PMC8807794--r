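#' Thermodynamic-integration estimate of the log model evidence
#'
#' The log evidence equals the integral over inverse temperature of the
#' expected log-likelihood under the power posterior,
#' \deqn{\ln p(y|m) = \int_0^1 E[\ln p(y|\theta,m)]_{p_\beta} \, d\beta.}
#' The per-temperature expectation is estimated by the Monte Carlo mean of
#' the cached log-likelihood samples, \eqn{E_{MC}(\beta_j)}, and the one
#' dimensional integral by the trapezoid rule on the temperature schedule:
#' \deqn{\ln p(y|m) \approx \tfrac12 \sum_j (\beta_{j+1} - \beta_j)
#'   (E_{MC}(\beta_{j+1}) + E_{MC}(\beta_j)).}
#' The Monte Carlo standard error is propagated from per-temperature
#' autocorrelation-corrected standard errors, treating temperatures as
#' independent.
#'
#' @param trace a `population_trace` whose schedule spans beta = 0 to 1 with
#'   at least one retained sample per chain.
#' @param rule quadrature rule: `"trapezoid"` (the default, and the rule the
#'   estimator is defined with) or `"simpson"` (composite Simpson on the
#'   irregular grid via piecewise quadratic interpolation; offered for
#'   sensitivity checks, never the default).
#' @return An object of class `evidence_estimate` with fields `method`
#'   (`"TI"`), `lme` (nats), `mc_se`, `curve` (a data frame of beta, E_MC and
#'   per-temperature MC standard error), `n_samples_used` and `seed`.
#' @export
ti_estimate <- function(trace, rule = c("trapezoid", "simpson")) {
  rule <- match.arg(rule)
  stopifnot(inherits(trace, "population_trace"))
  betas <- trace$schedule$betas
  if (betas[1] != 0 || betas[length(betas)] != 1)
    stop("invalid trace: schedule must include beta = 0 and beta = 1",
         call. = FALSE)
  if (trace$n_samples < 1L)
    stop("invalid trace: no retained samples", call. = FALSE)
  E <- colMeans(trace$loglik)
  if (any(!is.finite(E)))
    stop("non-finite E_MC at beta = ",
         paste(format(betas[!is.finite(E)], digits = 4), collapse = ", "),
         call. = FALSE)
  se <- apply(trace$loglik, 2, mc_se)
  lme <- if (rule == "simpson") simpson_irregular(betas, E)
  else trapezoid(betas, E)
  w <- trapezoid_weights(betas)
  est_se <- sqrt(sum((w * se)^2))
  evidence_estimate("TI", lme, mc_se = est_se,
                    curve = data.frame(beta = betas, E_MC = E, se = se),
                    n_samples_used = trace$n_samples, seed = trace$seed)
}

trapezoid <- function(x, y)
  0.5 * sum(diff(x) * (y[-1] + y[-length(y)]))

# Composite Simpson on an irregular grid: integrate the quadratic through
# each consecutive point triple over its two intervals; a leftover final
# interval falls back to the trapezoid.
simpson_irregular <- function(x, y) {
  n <- length(x)
  total <- 0
  j <- 1L
  while (j + 2L <= n) {
    x0 <- x[j]; x1 <- x[j + 1L]; x2 <- x[j + 2L]
    h0 <- x1 - x0; h1 <- x2 - x1; h <- h0 + h1
    total <- total + h / 6 * ((2 - h1 / h0) * y[j] +
                                h^2 / (h0 * h1) * y[j + 1L] +
                                (2 - h0 / h1) * y[j + 2L])
    j <- j + 2L
  }
  if (j + 1L <= n)
    total <- total + (x[j + 1L] - x[j]) * (y[j] + y[j + 1L]) / 2
  total
}

trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

evidence_estimate <- function(method, lme, mc_se = NA_real_, curve = NULL,
                              n_samples_used = NA_integer_,
                              seed = NA_integer_) {
  structure(list(method = method, lme = lme, mc_se = mc_se, curve = curve,
                 n_samples_used = n_samples_used, seed = seed),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("<evidence_estimate> %s: lme = %.3f nats", x$method, x$lme))
  if (is.finite(x$mc_se)) cat(sprintf(" (MC-SE %.3f)", x$mc_se))
  cat("\n")
  invisible(x)
}

# Numerically stable log(mean(exp(x))); -Inf entries are legitimate values.
log_mean_exp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' Prior arithmetic-mean estimate of the log evidence
#'
#' The evidence is the prior expectation of the likelihood, so
#' \eqn{\hat Z_{AME} = \frac1n \sum_k p(y|\theta_k)} with \eqn{\theta_k}
#' drawn from the prior; the log is computed with max-shift stabilization.
#' AME is a known *downward*-biased reference estimator (prior draws rarely
#' hit the high-likelihood region); it is included for benchmarking, not as
#' a recommended output.
#'
#' @param model a [bayes_model()].
#' @param n_samples number of prior draws (>= 1).
#' @param seed integer seed.
#' @return An `evidence_estimate` with method `"AME"`.
#' @export
ame_estimate <- function(model, n_samples, seed = 1L) {
  stopifnot(inherits(model, "bayes_model"), n_samples >= 1)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  th <- model$prior_sampler(as.integer(n_samples))
  ll <- vapply(seq_len(nrow(th)), function(k) eval_loglik(model, th[k, ]), 0)
  lme <- log_mean_exp(ll)
  if (lme == -Inf)
    stop("all prior-sample log-likelihoods are -Inf; AME undefined",
         call. = FALSE)
  evidence_estimate("AME", lme, n_samples_used = as.integer(n_samples),
                    seed = as.integer(seed))
}

#' Posterior harmonic-mean estimate of the log evidence
#'
#' The harmonic mean identity \eqn{1/Z = E[1/p(y|\theta)]_{posterior}} gives
#' \eqn{\hat Z_{HME}} as the harmonic mean of the likelihood over posterior
#' draws; computed as `-log_mean_exp(-loglik)`. HME is a known
#' *upward*-biased reference estimator with potentially infinite variance;
#' included for benchmarking only.
#'
#' @param x either a numeric vector of log-likelihood values sampled from the
#'   posterior, or a `population_trace` (whose beta = 1 chain is consumed).
#' @return An `evidence_estimate` with method `"HME"`.
#' @export
hme_estimate <- function(x) {
  if (inherits(x, "population_trace")) {
    betas <- x$schedule$betas
    j <- which(betas == 1)
    if (length(j) != 1L)
      stop("trace has no beta = 1 chain", call. = FALSE)
    ll <- x$loglik[, j]
    seed <- x$seed
    n <- x$n_samples
  } else {
    ll <- as.numeric(x)
    seed <- NA_integer_
    n <- length(ll)
  }
  ll <- ll[is.finite(ll)]
  if (length(ll) < 1L)
    stop("need at least one finite posterior log-likelihood sample",
         call. = FALSE)
  evidence_estimate("HME", -log_mean_exp(-ll), n_samples_used = length(ll),
                    seed = seed)
}

# Per-temperature Monte Carlo expected log-likelihood curve with MC-SE.
emc_curve <- function(trace) {
  stopifnot(inherits(trace, "population_trace"))
  data.frame(beta = trace$schedule$betas,
             E_MC = colMeans(trace$loglik),
             se = apply(trace$loglik, 2, mc_se))
}

#' Model-accuracy curve along the tempered path
#'
#' The accuracy \eqn{A(\beta)} — the expected log-likelihood under the power
#' posterior, i.e. the negative partial derivative of the free energy along
#' the path — estimated by \eqn{E_{MC}(\beta_j)} at every schedule
#' temperature. Since \eqn{\partial A/\partial \beta =
#' \mathrm{Var}[\ln p(y|\theta)] > 0}, the curve is monotonically increasing
#' up to Monte Carlo error; a monotonicity flag (within 2 combined MC
#' standard errors per adjacent pair) is attached.
#'
#' @param trace a `population_trace`.
#' @return Data frame with columns `beta`, `accuracy`, `se`;
#'   `attr(, "monotone")` is `TRUE` if no adjacent pair decreases by more
#'   than 2 combined standard errors.
#' @export
accuracy_curve <- function(trace) {
  e <- emc_curve(trace)
  out <- data.frame(beta = e$beta, accuracy = e$E_MC, se = e$se)
  d <- diff(out$accuracy)
  tol <- 2 * sqrt(out$se[-1]^2 + out$se[-nrow(out)]^2)
  attr(out, "monotone") <- all(d >= -tol)
  out
}

#' Accuracy/complexity decomposition of the free energy at a temperature
#'
#' At inverse temperature \eqn{\beta} the negative free energy decomposes as
#' \deqn{-F_H(\beta) = \beta A(\beta) - KL[p_\beta \,\|\, prior],}
#' i.e. accuracy minus complexity. The negative free energy is estimated by
#' the partial trapezoid integral of the accuracy curve from 0 to
#' \eqn{\beta}, and the KL term by the difference — nonnegative up to Monte
#' Carlo error. At beta = 1 the negative free energy is the log model
#' evidence and the KL term is the divergence of the posterior from the
#' prior.
#'
#' @param trace a `population_trace`.
#' @param beta_index index into the schedule (1-based).
#' @return List with `beta`, `neg_free_energy`, `accuracy_term`
#'   (\eqn{\beta A(\beta)}) and `kl_term`.
#' @export
decompose_free_energy <- function(trace, beta_index) {
  e <- emc_curve(trace)
  n <- nrow(e)
  beta_index <- as.integer(beta_index)
  if (beta_index < 1L || beta_index > n)
    stop("beta_index out of range", call. = FALSE)
  beta <- e$beta[beta_index]
  negF <- if (beta_index == 1L) 0 else
    trapezoid(e$beta[seq_len(beta_index)], e$E_MC[seq_len(beta_index)])
  acc <- beta * e$E_MC[beta_index]
  list(beta = beta, neg_free_energy = negF, accuracy_term = acc,
       kl_term = acc - negF)
}

#' Estimate the log model evidence of a Bayesian model
#'
#' The top-level fitting function: runs the population MCMC sampler over a
#' power-rule temperature schedule and applies the requested evidence
#' estimators — thermodynamic integration (recommended) plus, optionally, the
#' known-biased prior arithmetic-mean and posterior harmonic-mean references.
#' AME consumes fresh prior draws (`n_chains * n_samples` of them, matching
#' TI's total sampling budget); HME consumes the beta = 1 chain of the trace.
#'
#' @param model a [bayes_model()].
#' @param methods subset of `c("ti", "ame", "hme")`.
#' @param n_chains number of temperatures (default 16).
#' @param order power-rule exponent of the schedule (default 5).
#' @param n_samples retained sweeps per chain (default 1500).
#' @param burn_in discarded sweeps (default `n_samples %/% 3`).
#' @param seed integer seed.
#' @param ... further arguments to [run_population_mcmc()].
#' @return An object of class `evidence_fit`: a list with `estimates` (named
#'   list of `evidence_estimate`), `trace`, and the call configuration.
#'   `print()`, `summary()` and `plot()` methods are provided; `plot()` draws
#'   the expected log-likelihood curve over beta whose area is the TI
#'   estimate.
#' @export
model_evidence <- function(model, methods = c("ti", "ame", "hme"),
                           n_chains = 16, order = 5, n_samples = 1500,
                           burn_in = n_samples %/% 3, seed = 1L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  schedule <- power_schedule(n_chains, order)
  trace <- run_population_mcmc(model, schedule, n_samples = n_samples,
                               burn_in = burn_in, seed = seed, ...)
  est <- list()
  if ("ti" %in% methods) est$ti <- ti_estimate(trace)
  if ("ame" %in% methods)
    est$ame <- ame_estimate(model, n_samples = n_chains * n_samples,
                            seed = seed + 1L)
  if ("hme" %in% methods) est$hme <- hme_estimate(trace)
  structure(list(estimates = est, trace = trace, model_name = model$name,
                 n_chains = n_chains, order = order, n_samples = n_samples,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "evidence_fit")
}

#' @export
print.evidence_fit <- function(x, ...) {
  cat("Log model evidence for", x$model_name, "\n")
  for (e in x$estimates)
    cat(sprintf("  %-4s %10.3f nats%s\n", e$method, e$lme,
                if (is.finite(e$mc_se)) sprintf("  (MC-SE %.3f)", e$mc_se)
                else ""))
  invisible(x)
}

#' @export
summary.evidence_fit <- function(object, ...) {
  rh <- split_rhat(object$trace)
  cat("Population MCMC:", x_fmt(object$n_chains), "chains (order",
      object$order, "schedule),", object$n_samples, "retained sweeps,",
      object$burn_in, "burn-in, seed", object$seed, "\n")
  cat("Max split-half R-hat of log-likelihood:",
      sprintf("%.4f", attr(rh, "max")), "\n")
  cat("Within-chain acceptance range:",
      paste(sprintf("%.2f", range(object$trace$acceptance$within)),
            collapse = " - "), "\n\n")
  print.evidence_fit(object)
  invisible(object)
}

x_fmt <- function(n) format(n, big.mark = ",")

#' @export
plot.evidence_fit <- function(x, ...) {
  plot.population_trace(x$trace, ...)
  if (!is.null(x$estimates$ti))
    graphics::legend("bottomright", bty = "n",
                     legend = sprintf("TI lme = %.2f nats",
                                      x$estimates$ti$lme))
  invisible(x)
}

#' Serialize an evidence estimate to JSON / its curve to CSV
#'
#' @param est an `evidence_estimate`.
#' @param path output file path.
#' @export
write_evidence_json <- function(est, path) {
  stopifnot(inherits(est, "evidence_estimate"))
  jsonlite::write_json(
    list(method = est$method, lme = est$lme, mc_se = est$mc_se,
         n_samples_used = est$n_samples_used, seed = est$seed),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_evidence_json
#' @export
write_evidence_curve_csv <- function(est, path) {
  stopifnot(inherits(est, "evidence_estimate"))
  if (is.null(est$curve)) stop("estimate has no curve", call. = FALSE)
  utils::write.csv(est$curve, path, row.names = FALSE)
  invisible(path)
}
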