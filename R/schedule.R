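#' Power-rule temperature schedule
#'
#' The inverse-temperature grid defining the tempered path from the prior
#' (beta = 0) to the posterior (beta = 1):
#' \deqn{\beta_j = \left(\frac{j}{N-1}\right)^{order}, \quad j = 0, \dots, N-1.}
#' A fifth-order rule (the default) concentrates temperatures near beta = 0,
#' where the expected log-likelihood curve of most models is steepest.
#'
#' @param n_chains number of temperatures N (>= 2).
#' @param order power-rule exponent (> 0); `order = 1` gives a uniform grid.
#' @return An object of class `temperature_schedule` with fields `betas`
#'   (strictly increasing, endpoints exactly 0 and 1) and `order`.
#' @export
power_schedule <- function(n_chains, order = 5) {
  n_chains <- as.integer(n_chains)
  if (is.na(n_chains) || n_chains < 2L)
    stop("n_chains must be an integer >= 2", call. = FALSE)
  if (!is.numeric(order) || order <= 0)
    stop("order must be > 0", call. = FALSE)
  betas <- (seq_len(n_chains) - 1)^order / (n_chains - 1)^order
  structure(list(betas = betas, order = order),
            class = "temperature_schedule")
}

#' @export
print.temperature_schedule <- function(x, ...) {
  cat("<temperature_schedule>", length(x$betas), "temperatures, order",
      x$order, "\n")
  invisible(x)
}

as_schedule <- function(x) {
  if (inherits(x, "temperature_schedule")) return(x)
  betas <- as.numeric(x)
  if (length(betas) < 2 || betas[1] != 0 || betas[length(betas)] != 1 ||
      any(diff(betas) <= 0))
    stop("a schedule must be strictly increasing from 0 to 1", call. = FALSE)
  structure(list(betas = betas, order = NA_real_),
            class = "temperature_schedule")
}
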