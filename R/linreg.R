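#' Conjugate Bayesian linear regression with analytic evidence
#'
#' The model is \deqn{\theta \sim N(0, \Pi_p^{-1}), \quad
#'   y \sim N(X\theta, \Pi_e^{-1})} with known prior precision \eqn{\Pi_p}
#' (p x p) and noise precision \eqn{\Pi_e} (M x M). Because prior and
#' likelihood are jointly Gaussian, the log model evidence and the posterior
#' moments are available in closed form, which makes the family the standard
#' oracle for validating sampling-based evidence estimators.
#'
#' @param design M x p design matrix X.
#' @param data length-M observation vector y.
#' @param prior_precision p x p symmetric positive definite matrix.
#' @param noise_precision M x M symmetric positive definite matrix.
#' @param name model identifier.
#'
#' @return An object of classes `linreg_model` and `bayes_model`. In addition
#'   to the generic contract it carries `design`, `data`, `prior_precision`
#'   and `noise_precision`.
#' @export
linreg_model <- function(design, data, prior_precision, noise_precision,
                         name = "linreg") {
  design <- as.matrix(design)
  data <- as.numeric(data)
  prior_precision <- as.matrix(prior_precision)
  noise_precision <- as.matrix(noise_precision)
  M <- nrow(design)
  p <- ncol(design)
  if (length(data) != M)
    stop("length(data) must equal nrow(design)", call. = FALSE)
  if (!all(dim(prior_precision) == c(p, p)))
    stop("prior_precision must be ", p, " x ", p, call. = FALSE)
  if (!all(dim(noise_precision) == c(M, M)))
    stop("noise_precision must be ", M, " x ", M, call. = FALSE)
  Up <- chol_spd(prior_precision, "prior_precision")
  Ue <- chol_spd(noise_precision, "noise_precision")

  # Constants of the Gaussian log densities, precomputed once.
  ldet_p <- 2 * sum(log(diag(Up)))
  ldet_e <- 2 * sum(log(diag(Ue)))
  lp_const <- 0.5 * (ldet_p - p * log(2 * pi))
  ll_const <- 0.5 * (ldet_e - M * log(2 * pi))

  log_prior <- function(theta) {
    z <- Up %*% theta
    lp_const - 0.5 * sum(z * z)
  }
  log_likelihood <- function(theta) {
    r <- data - design %*% theta
    z <- Ue %*% r
    ll_const - 0.5 * sum(z * z)
  }
  prior_sampler <- function(n) {
    z <- matrix(stats::rnorm(n * p), n, p)
    # theta = Up^{-1} z has covariance (Up'Up)^{-1} = prior_precision^{-1}
    t(backsolve(Up, t(z)))
  }

  m <- bayes_model(name, p, log_prior, log_likelihood, prior_sampler)
  m$design <- design
  m$data <- data
  m$prior_precision <- prior_precision
  m$noise_precision <- noise_precision
  class(m) <- c("linreg_model", class(m))
  m
}

# Cholesky with an explicit SPD error message.
chol_spd <- function(S, what) {
  if (!isSymmetric(S, tol = 1e-8))
    stop(what, " must be symmetric positive definite", call. = FALSE)
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out))
    stop(what, " must be symmetric positive definite", call. = FALSE)
  out
}

#' Analytic log model evidence of a conjugate linear regression
#'
#' Evaluates the closed-form marginal likelihood
#' \deqn{\ln p(y) = \tfrac12\big(-\ln|\Pi| - M\ln 2\pi + \ln|\Pi_e| +
#'   \ln|\Pi_p| - (y - X\eta)^\top \Pi_e (y - X\eta) -
#'   \eta^\top \Pi_p \eta\big)}
#' where \eqn{\Pi = \Pi_p + X^\top \Pi_e X} and
#' \eqn{\eta = \Pi^{-1} X^\top \Pi_e y} are the posterior precision and mean.
#' All determinants and solves go through Cholesky factorizations; no
#' explicit inverse is ever formed.
#'
#' @param model a `linreg_model`.
#' @return The log evidence in nats (a scalar); deterministic.
#' @export
linreg_log_evidence <- function(model) {
  stopifnot(inherits(model, "linreg_model"))
  X <- model$design
  y <- model$data
  Pp <- model$prior_precision
  Pe <- model$noise_precision
  M <- nrow(X)
  post <- linreg_posterior(model)
  eta <- post$mean
  U <- chol(post$precision)
  ldet_post <- 2 * sum(log(diag(U)))
  ldet_p <- 2 * sum(log(diag(chol(Pp))))
  ldet_e <- 2 * sum(log(diag(chol(Pe))))
  r <- y - X %*% eta
  0.5 * (-ldet_post - M * log(2 * pi) + ldet_e + ldet_p -
           drop(crossprod(r, Pe %*% r)) - drop(crossprod(eta, Pp %*% eta)))
}

#' Exact conjugate posterior of a linear regression model
#'
#' @param model a `linreg_model`.
#' @return A list with `mean` (length p) and `precision` (p x p), the exact
#'   Gaussian posterior moments \eqn{\Pi = \Pi_p + X^\top \Pi_e X},
#'   \eqn{\eta = \Pi^{-1} X^\top \Pi_e y}. Used as ground truth when
#'   validating the beta = 1 chain of the population sampler.
#' @export
linreg_posterior <- function(model) {
  stopifnot(inherits(model, "linreg_model"))
  X <- model$design
  Pe <- model$noise_precision
  Pi <- model$prior_precision + crossprod(X, Pe %*% X)
  Pi <- (Pi + t(Pi)) / 2
  b <- crossprod(X, Pe %*% model$data)
  U <- chol_spd(Pi, "posterior precision")
  mean <- backsolve(U, forwardsolve(t(U), b))
  list(mean = drop(mean), precision = Pi)
}

#' Generate a one-way ANOVA benchmark dataset
#'
#' Builds the block design used throughout the estimator benchmark: a one-hot
#' design for a one-way ANOVA with `p` levels and `M` observations,
#' `floor(M/p)` rows per level with the excess data points assigned to the
#' last cell. Regression coefficients are drawn from the prior
#' N(0, prior_var I) and observations from the likelihood
#' N(X theta, noise_var I); given `seed` the theta draw consumes the RNG
#' stream first, then the noise draw, so datasets are bit-reproducible.
#'
#' @param p number of ANOVA levels (regression parameters), 1 <= p <= M.
#' @param M number of observations.
#' @param prior_var prior variance of each coefficient (default 16).
#' @param noise_var observation noise variance (default 10).
#' @param seed integer master seed for the dataset.
#' @return A `linreg_model` whose attribute `"theta_true"` holds the
#'   generating coefficients and whose name records p, M and the seed.
#' @export
generate_linreg_dataset <- function(p, M, prior_var = 16, noise_var = 10,
                                    seed = 1L) {
  p <- as.integer(p); M <- as.integer(M)
  if (p < 1L || p > M)
    stop("need 1 <= p <= M", call. = FALSE)
  sizes <- rep(M %/% p, p)
  sizes[p] <- sizes[p] + M %% p   # excess data points to the last cell
  X <- matrix(0, M, p)
  X[cbind(seq_len(M), rep(seq_len(p), sizes))] <- 1
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  theta <- stats::rnorm(p, 0, sqrt(prior_var))
  y <- drop(X %*% theta) + stats::rnorm(M, 0, sqrt(noise_var))
  m <- linreg_model(X, y, diag(1 / prior_var, p), diag(1 / noise_var, M),
                    name = sprintf("linreg_p%d_M%d_seed%d", p, M, seed))
  attr(m, "theta_true") <- theta
  m
}

#' Write / read a linear regression model as plain text
#'
#' Round-trips a `linreg_model` to a directory holding `design.csv` (the
#' design matrix), `data.csv` (the observation vector) and `model.json`
#' (precision matrices as nested arrays plus the model name).
#'
#' @param model a `linreg_model`.
#' @param dir directory to write to (created if missing).
#' @return `write_linreg_model` returns `dir` invisibly; `read_linreg_model`
#'   returns the reconstructed `linreg_model`.
#' @export
write_linreg_model <- function(model, dir) {
  stopifnot(inherits(model, "linreg_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(model$design),
                   file.path(dir, "design.csv"), row.names = FALSE)
  utils::write.csv(data.frame(y = model$data),
                   file.path(dir, "data.csv"), row.names = FALSE)
  meta <- list(name = model$name,
               prior_precision = model$prior_precision,
               noise_precision = model$noise_precision)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_linreg_model
#' @export
read_linreg_model <- function(dir) {
  X <- as.matrix(utils::read.csv(file.path(dir, "design.csv")))
  dimnames(X) <- NULL
  y <- utils::read.csv(file.path(dir, "data.csv"))$y
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  linreg_model(X, y, as.matrix(meta$prior_precision),
               as.matrix(meta$noise_precision), name = meta$name)
}

# Run code under a temporary seed, restoring the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
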