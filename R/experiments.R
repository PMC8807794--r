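#' Estimator-accuracy benchmark on conjugate linear models
#'
#' For each number of ANOVA levels `p` and each repetition, generates a fresh
#' dataset from the conjugate linear-regression generative model
#' ([generate_linreg_dataset()]), estimates the log evidence by TI, AME and
#' HME, and records the error relative to the analytic evidence
#' ([linreg_log_evidence()]). Defaults follow the benchmark conditions
#' (M = 100, prior variance 16, noise variance 10); the default sampler
#' settings (16 chains, order-5 schedule, 1500 retained sweeps, 10
#' repetitions) are a desk-scale reduction of the full study (64 chains,
#' 6000 samples, p from 2 to 32).
#'
#' @param p_values integer vector of model dimensions.
#' @param n_reps repetitions (fresh dataset each) per p.
#' @param M,prior_var,noise_var dataset parameters.
#' @param n_chains,order,n_samples,burn_in sampler settings.
#' @param seed master seed; dataset and run seeds are derived from it
#'   deterministically.
#' @return A list with `summary` (data frame of p, method, error_mean,
#'   error_sd, n_reps) and `errors` (data frame of per-repetition errors).
#' @export
run_linreg_benchmark <- function(p_values = c(2, 8, 16), n_reps = 10,
                                 M = 100, prior_var = 16, noise_var = 10,
                                 n_chains = 16, order = 5, n_samples = 1500,
                                 burn_in = 500, seed = 1L) {
  stopifnot(all(p_values <= M))
  rows <- list()
  for (p in p_values) {
    for (rep in seq_len(n_reps)) {
      ds_seed <- seed + 1000L * p + rep
      model <- generate_linreg_dataset(p, M, prior_var, noise_var,
                                       seed = ds_seed)
      analytic <- linreg_log_evidence(model)
      fit <- model_evidence(model, methods = c("ti", "ame", "hme"),
                            n_chains = n_chains, order = order,
                            n_samples = n_samples, burn_in = burn_in,
                            seed = ds_seed + 1L)
      for (m in names(fit$estimates))
        rows[[length(rows) + 1L]] <- data.frame(
          p = p, rep = rep, method = toupper(m),
          error = fit$estimates[[m]]$lme - analytic,
          analytic = analytic)
    }
  }
  errors <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(errors, errors[c("p", "method")]),
                                   function(g) data.frame(
                                     p = g$p[1], method = g$method[1],
                                     error_mean = mean(g$error),
                                     error_sd = stats::sd(g$error),
                                     n_reps = nrow(g))))
  rownames(summary) <- NULL
  list(summary = summary[order(summary$p, summary$method), ],
       errors = errors)
}

#' Model-recovery study on simulated DCM data
#'
#' For every generating specification, simulates the noiseless BOLD signal
#' once, corrupts it with `n_datasets` independent Gaussian noise
#' realizations at the given SNR (the underlying time series stays constant),
#' inverts each dataset under every candidate specification with each
#' requested estimator, and counts which model attains the largest estimated
#' log evidence. Ties in the argmax are counted as incorrect (with a
#' warning); inversions that fail outright are recorded in the `failures`
#' log, never silently dropped.
#'
#' @param specs list of `dcm_spec` candidates (>= 2).
#' @param n_datasets noise realizations per generating model.
#' @param snr signal-to-noise ratio of the simulated data.
#' @param estimators subset of `c("ti", "ame", "hme")`.
#' @param n_chains,order,n_samples,burn_in sampler settings per inversion.
#' @param seed master seed.
#' @return A named list of `recovery_table` objects (one per estimator):
#'   counts matrices with rows = inverting model, columns = generating model
#'   (column sums equal `n_datasets`), plus a `failures` data frame.
#' @export
run_model_recovery <- function(specs, n_datasets = 5, snr = 1,
                               estimators = "ti", n_chains = 16, order = 5,
                               n_samples = 2000, burn_in = 1000, seed = 1L) {
  stopifnot(length(specs) >= 2)
  nm <- vapply(specs, function(s) s$name, "")
  n_m <- length(specs)
  counts <- lapply(estimators, function(e)
    matrix(0L, n_m, n_m, dimnames = list(inverting = nm, generating = nm)))
  names(counts) <- estimators
  failures <- list()

  signals <- lapply(specs, integrate_dcm)
  for (g in seq_len(n_m)) {
    for (ds in seq_len(n_datasets)) {
      noise_seed <- seed + 10000L * g + ds
      dat <- add_noise_at_snr(signals[[g]], snr, seed = noise_seed)
      lmes <- matrix(NA_real_, n_m, length(estimators),
                     dimnames = list(nm, estimators))
      for (i in seq_len(n_m)) {
        model <- dcm_model(specs[[i]], dat$observed)
        fit <- tryCatch(
          model_evidence(model, methods = estimators, n_chains = n_chains,
                         order = order, n_samples = n_samples,
                         burn_in = burn_in, seed = noise_seed + i),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            generating = nm[g], dataset = ds, inverting = nm[i],
            message = conditionMessage(fit))
          next
        }
        for (e in estimators)
          lmes[i, e] <- fit$estimates[[e]]$lme
      }
      for (e in estimators) {
        v <- lmes[, e]
        if (any(is.na(v))) next
        top <- which(v == max(v))
        if (length(top) > 1L) {
          warning("tied log-evidence argmax for generating model ", nm[g],
                  ", dataset ", ds, "; counted as incorrect", call. = FALSE)
          next
        }
        counts[[e]][top, g] <- counts[[e]][top, g] + 1L
      }
    }
  }
  out <- lapply(estimators, function(e)
    structure(list(method = toupper(e), counts = counts[[e]],
                   n_datasets_per_model = n_datasets),
              class = "recovery_table"))
  names(out) <- estimators
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
  else NULL
  out
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("<recovery_table>", x$method, "- rows: inverting model, columns:",
      "generating model (", x$n_datasets_per_model, "datasets each)\n")
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square comparison of two recovery rates
#'
#' Tests whether two inference methods differ in how often they select the
#' data-generating model, via the Pearson chi-square statistic (1 df, no
#' continuity correction) on the 2 x 2 table of correct/incorrect counts.
#' A zero marginal (both methods all-correct or all-incorrect) yields
#' chi-square = 0 with a warning.
#'
#' @param correct_a,total_a correct selections and total inversions, method A.
#' @param correct_b,total_b the same for method B.
#' @return List with `chi2` and `p` (upper tail of chi-square with 1 df).
#' @export
chi_square_recovery <- function(correct_a, total_a, correct_b, total_b) {
  stopifnot(total_a >= 1, total_b >= 1,
            correct_a >= 0, correct_a <= total_a,
            correct_b >= 0, correct_b <= total_b)
  tab <- rbind(c(correct_a, total_a - correct_a),
               c(correct_b, total_b - correct_b))
  cs <- colSums(tab)
  if (any(cs == 0)) {
    warning("degenerate 2x2 table (a zero marginal); chi-square set to 0",
            call. = FALSE)
    return(list(chi2 = 0, p = 1))
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), cs) / n
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
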