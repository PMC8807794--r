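#' Power posterior of a Bayesian model
#'
#' The tempered density with unnormalized log-density
#' \eqn{\beta \ln p(y|\theta) + \ln p(\theta)}: the prior at beta = 0 and the
#' posterior at beta = 1. At beta = 0 the likelihood does not influence the
#' density (the convention `0 * (-Inf) = 0` is applied, so parameter draws
#' with diverged likelihoods are still valid prior samples).
#'
#' @param model a [bayes_model()].
#' @param beta inverse temperature in [0, 1].
#' @return An object of class `power_posterior`.
#' @export
power_posterior <- function(model, beta) {
  stopifnot(inherits(model, "bayes_model"),
            is.numeric(beta), beta >= 0, beta <= 1)
  structure(list(model = model, beta = beta), class = "power_posterior")
}

# beta * loglik + logprior with the beta = 0 convention.
tempered_logdens <- function(beta, loglik, logprior) {
  if (beta == 0) logprior else beta * loglik + logprior
}

# Metropolis accept/reject on a log ratio; -Inf proposals always rejected,
# moves away from a -Inf current state always accepted.
mh_accept <- function(cur, new) {
  if (new == -Inf) return(FALSE)
  if (cur == -Inf) return(TRUE)
  log(stats::runif(1)) < (new - cur)
}

#' One Metropolis-Hastings random-walk update under a power posterior
#'
#' Proposes `state + proposal_scale * z` with `z` standard normal and accepts
#' with probability `min(1, exp(delta))` where `delta` is the change in
#' `beta * log_likelihood + log_prior`.
#'
#' @param state current parameter vector.
#' @param pp a [power_posterior()].
#' @param proposal_scale scalar or per-coordinate vector of proposal standard
#'   deviations.
#' @param loglik,logprior optional cached values at `state` (recomputed when
#'   missing).
#' @return List with `state`, `loglik`, `logprior`, `accepted`.
#' @export
mh_step <- function(state, pp, proposal_scale, loglik = NULL,
                    logprior = NULL) {
  stopifnot(inherits(pp, "power_posterior"))
  model <- pp$model
  beta <- pp$beta
  if (is.null(loglik)) loglik <- eval_loglik(model, state)
  if (is.null(logprior)) logprior <- model$log_prior(state)
  prop <- state + proposal_scale * stats::rnorm(length(state))
  ll_new <- eval_loglik(model, prop)
  lp_new <- model$log_prior(prop)
  cur <- tempered_logdens(beta, loglik, logprior)
  new <- tempered_logdens(beta, ll_new, lp_new)
  if (mh_accept(cur, new))
    list(state = prop, loglik = ll_new, logprior = lp_new, accepted = TRUE)
  else
    list(state = state, loglik = loglik, logprior = logprior,
         accepted = FALSE)
}

#' Log acceptance ratio of a between-chain swap move
#'
#' Exchanging the states of the chains at inverse temperatures `beta_i` and
#' `beta_j` is accepted with probability
#' \eqn{\min(1, \exp((\beta_i - \beta_j)(\ell_j - \ell_i)))} where
#' \eqn{\ell} are the cached log-likelihoods. Equal temperatures or equal
#' states give a ratio of 0 (always accepted).
#'
#' @param beta_i,beta_j the two inverse temperatures.
#' @param loglik_i,loglik_j cached log-likelihoods of the two states.
#' @return The log acceptance ratio (possibly `Inf`).
#' @export
swap_log_ratio <- function(beta_i, beta_j, loglik_i, loglik_j) {
  if (beta_i == beta_j) return(0)
  if (loglik_i == loglik_j) return(0)
  (beta_i - beta_j) * (loglik_j - loglik_i)
}

#' Population MCMC over a temperature schedule
#'
#' Runs one Metropolis-Hastings chain per inverse temperature with
#' between-chain swap moves. Each sweep performs one random-walk update per
#' chain followed by a swap pass over alternating even/odd adjacent pairs
#' (all adjacencies are visited every two sweeps). The beta = 0 chain is
#' sampled by independent draws from the prior (exact, since the power
#' posterior at beta = 0 is the prior itself). Proposals are adapted per
#' chain during burn-in — a Robbins-Monro update of a global log step-size
#' toward `target_accept`, plus periodic re-estimation of per-coordinate
#' scales from the chain's own recent draws (diagonal adaptive Metropolis) —
#' and frozen afterwards, so the retained samples come from a valid
#' (non-adaptive) kernel. Given `seed` the trace is bit-reproducible.
#'
#' @param model a [bayes_model()].
#' @param schedule a [power_schedule()] (or a numeric beta grid from 0 to 1).
#' @param n_samples retained sweeps per chain (K >= 0).
#' @param burn_in discarded adaptation sweeps (>= 0).
#' @param seed integer seed for the whole run.
#' @param target_accept within-chain acceptance target for adaptation.
#' @param swap_every perform a swap pass every `swap_every` sweeps.
#' @param adapt adapt proposal scales during burn-in.
#' @param init_scale optional initial per-coordinate proposal scale; by
#'   default 2.38/sqrt(dim) times a per-coordinate prior scale estimated from
#'   prior draws.
#' @return An object of class `population_trace`: schedule, per-temperature
#'   draws (list of K x dim matrices), cached log-likelihood and log-prior
#'   matrices (K x n_chains), within-chain and swap acceptance rates,
#'   burn-in bookkeeping and the seed.
#' @export
run_population_mcmc <- function(model, schedule, n_samples, burn_in = 0L,
                                seed = 1L, target_accept = 0.25,
                                swap_every = 1L, adapt = TRUE,
                                init_scale = NULL) {
  stopifnot(inherits(model, "bayes_model"))
  schedule <- as_schedule(schedule)
  betas <- schedule$betas
  n_beta <- length(betas)
  n_samples <- as.integer(n_samples)
  burn_in <- as.integer(burn_in)
  stopifnot(n_samples >= 0L, burn_in >= 0L, swap_every >= 1L)
  d <- model$dim

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  # Per-coordinate proposal scale: prior spread scaled by the classic
  # 2.38/sqrt(d) random-walk factor, then adapted per chain on the log scale.
  if (is.null(init_scale)) {
    ref <- model$prior_sampler(128L)
    base_scale <- pmax(apply(ref, 2, stats::sd), 1e-8) * 2.38 / sqrt(d)
  } else {
    base_scale <- rep_len(init_scale, d)
  }
  scale_mat <- matrix(base_scale, n_beta, d, byrow = TRUE)  # per chain
  log_scale <- rep(0, n_beta)  # global multiplier, per chain
  # Welford-style window accumulators for the diagonal covariance adaptation
  adapt_every <- 100L
  win_n <- 0L
  win_sum <- matrix(0, n_beta, d)
  win_ss <- matrix(0, n_beta, d)

  states <- model$prior_sampler(n_beta)      # one row per chain
  loglik <- numeric(n_beta)
  logprior <- numeric(n_beta)
  for (j in seq_len(n_beta)) {
    loglik[j] <- eval_loglik(model, states[j, ])
    logprior[j] <- model$log_prior(states[j, ])
  }

  draws <- array(NA_real_, dim = c(max(n_samples, 0L), d, n_beta))
  ll_out <- matrix(NA_real_, n_samples, n_beta)
  lp_out <- matrix(NA_real_, n_samples, n_beta)
  acc_count <- integer(n_beta)       # post-burn-in within-chain accepts
  swap_attempt <- integer(n_beta - 1L)
  swap_accept <- integer(n_beta - 1L)

  total <- burn_in + n_samples
  for (t in seq_len(total)) {
    post <- t > burn_in
    for (j in seq_len(n_beta)) {
      if (betas[j] == 0) {
        # exact independent draw from the prior
        st <- model$prior_sampler(1L)[1L, ]
        states[j, ] <- st
        loglik[j] <- eval_loglik(model, st)
        logprior[j] <- model$log_prior(st)
        if (post) acc_count[j] <- acc_count[j] + 1L
        next
      }
      scale_j <- scale_mat[j, ] * exp(log_scale[j])
      prop <- states[j, ] + scale_j * stats::rnorm(d)
      ll_new <- eval_loglik(model, prop)
      lp_new <- model$log_prior(prop)
      cur <- tempered_logdens(betas[j], loglik[j], logprior[j])
      new <- tempered_logdens(betas[j], ll_new, lp_new)
      acc <- mh_accept(cur, new)
      if (acc) {
        states[j, ] <- prop
        loglik[j] <- ll_new
        logprior[j] <- lp_new
      }
      if (!post && adapt)
        log_scale[j] <- log_scale[j] +
          t^(-0.6) * ((if (acc) 1 else 0) - target_accept)
      if (post && acc) acc_count[j] <- acc_count[j] + 1L
    }
    if (n_beta > 1L && t %% swap_every == 0L) {
      first <- if ((t %/% swap_every) %% 2L == 1L) 1L else 2L
      js <- seq.int(first, n_beta - 1L, by = 2L)
      for (j in js) {
        swap_attempt[j] <- swap_attempt[j] + 1L
        lr <- swap_log_ratio(betas[j], betas[j + 1L],
                             loglik[j], loglik[j + 1L])
        if (lr >= 0 || log(stats::runif(1)) < lr) {
          tmp <- states[j, ]; states[j, ] <- states[j + 1L, ]
          states[j + 1L, ] <- tmp
          loglik[c(j, j + 1L)] <- loglik[c(j + 1L, j)]
          logprior[c(j, j + 1L)] <- logprior[c(j + 1L, j)]
          swap_accept[j] <- swap_accept[j] + 1L
        }
      }
    }
    if (!post && adapt) {
      win_n <- win_n + 1L
      win_sum <- win_sum + states
      win_ss <- win_ss + states^2
      if (t %% adapt_every == 0L && win_n >= 50L) {
        mu <- win_sum / win_n
        sds <- sqrt(pmax(win_ss / win_n - mu^2, 0))
        upd <- sds * (2.38 / sqrt(d))
        keep <- upd > 0
        scale_mat[keep] <- upd[keep]
        win_n <- 0L
        win_sum[] <- 0
        win_ss[] <- 0
      }
    }
    if (post) {
      k <- t - burn_in
      draws[k, , ] <- t(states)
      ll_out[k, ] <- loglik
      lp_out[k, ] <- logprior
    }
  }

  within_rate <- if (n_samples > 0) acc_count / n_samples else
    rep(NA_real_, n_beta)
  swap_rate <- ifelse(swap_attempt > 0, swap_accept / swap_attempt, NA_real_)
  if (n_samples > 0 && all(within_rate[betas > 0] == 0))
    warning("all tempered chains rejected every post-burn-in proposal; ",
            "the sampler appears stuck", call. = FALSE)

  structure(
    list(schedule = schedule,
         draws = lapply(seq_len(n_beta), function(j)
           matrix(draws[, , j], nrow = n_samples, ncol = d)),
         loglik = ll_out, logprior = lp_out,
         acceptance = list(within = within_rate, swap = swap_rate),
         burn_in = burn_in, n_samples = n_samples, seed = as.integer(seed),
         proposal_scale = scale_mat * exp(log_scale),
         model_name = model$name, dim = d),
    class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  cat("<population_trace>", x$model_name, ":", length(x$schedule$betas),
      "temperatures x", x$n_samples, "retained sweeps (burn-in",
      paste0(x$burn_in, ")\n"))
  if (x$n_samples > 0) {
    cat("  within-chain acceptance:",
        paste(sprintf("%.2f", range(x$acceptance$within)), collapse = " - "),
        "\n")
    sr <- x$acceptance$swap
    if (length(sr) && any(is.finite(sr)))
      cat("  swap acceptance:",
          paste(sprintf("%.2f", range(sr, na.rm = TRUE)), collapse = " - "),
          "\n")
  }
  invisible(x)
}

#' @export
plot.population_trace <- function(x, ...) {
  e <- emc_curve(x)
  graphics::plot(e$beta, e$E_MC, type = "b", pch = 16,
                 xlab = expression(beta),
                 ylab = "E[ln p(y | theta)] under power posterior",
                 main = x$model_name, ...)
  graphics::arrows(e$beta, e$E_MC - 2 * e$se, e$beta, e$E_MC + 2 * e$se,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  invisible(x)
}
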