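#' Gelman-Rubin potential scale reduction factor
#'
#' Classical R-hat comparing between- and within-segment variance of a scalar
#' chain quantity: with m segments of length n, sample means
#' \eqn{\bar x_j} and variances \eqn{s_j^2},
#' \deqn{W = \frac1m \sum s_j^2, \quad B/n = \mathrm{Var}(\bar x_j), \quad
#'   \hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}.}
#' When every segment has zero within-variance the statistic is defined as
#' exactly 1 (degenerate-trace convention).
#'
#' @param segments a list of equal-length numeric vectors, or a matrix with
#'   one segment per column; at least 2 segments of length >= 4.
#' @return The scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(segments) {
  if (is.matrix(segments))
    segments <- lapply(seq_len(ncol(segments)), function(j) segments[, j])
  m <- length(segments)
  if (m < 2L) stop("need at least 2 segments", call. = FALSE)
  n <- unique(lengths(segments))
  if (length(n) != 1L) stop("segments must have equal length", call. = FALSE)
  if (n < 4L) stop("segments must have length >= 4", call. = FALSE)
  means <- vapply(segments, mean, 0)
  vars <- vapply(segments, stats::var, 0)
  W <- mean(vars)
  if (W == 0) return(1)
  B_over_n <- stats::var(means)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Split-half R-hat of the log-likelihood, per temperature
#'
#' Because the chains of a population sampler target different distributions,
#' convergence is assessed per temperature: the retained log-likelihood trace
#' of each chain is split into two halves and the Gelman-Rubin statistic is
#' computed on the pair. The conventional summary is the maximum over
#' temperatures (values below 1.1 are read as converged).
#'
#' @param trace a `population_trace`.
#' @return Named numeric vector of split-half R-hat values, one per
#'   temperature; `attr(, "max")` holds the maximum.
#' @export
split_rhat <- function(trace) {
  stopifnot(inherits(trace, "population_trace"))
  K <- trace$n_samples
  if (K < 8L) stop("need at least 8 retained sweeps", call. = FALSE)
  half <- K %/% 2L
  out <- vapply(seq_len(ncol(trace$loglik)), function(j) {
    x <- trace$loglik[, j]
    gelman_rubin(list(x[seq_len(half)], x[seq.int(K - half + 1L, K)]))
  }, 0)
  names(out) <- format(trace$schedule$betas, digits = 3)
  attr(out, "max") <- max(out)
  out
}

#' Effective sample size of a correlated scalar chain
#'
#' Autocorrelation-aware effective sample size using the initial positive
#' sequence truncation: the integrated autocorrelation time is
#' \eqn{\tau = 1 + 2\sum_t \rho_t}, with the sum stopped at the first
#' non-positive pair sum of autocorrelations; `ess = n / tau`, capped at n.
#'
#' @param x numeric vector of MCMC draws of a scalar quantity.
#' @return Effective number of independent draws (>= 1).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(as.numeric(n))
  lag_max <- min(n - 2L, max(10L, floor(10 * sqrt(n))))
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(1, min(n, n / tau))
}

# Monte Carlo standard error of the mean of a correlated chain.
mc_se <- function(x) stats::sd(x) / sqrt(ess(x))
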