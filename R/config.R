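#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration, validates it against the schema
#' below, rejects unknown keys, and resolves all defaults so the returned
#' object fully describes the run.
#'
#' Schema (top-level sections):
#' \itemize{
#'   \item `model`: `family` (`"linreg"` or `"dcm"`); for linreg: `p`, `M`,
#'     `prior_var`, `noise_var`, `dataset_seed`, or `dir` pointing at a
#'     serialized model; for dcm: `fixture` (`"m1"`..`"m5"`), `snr`,
#'     `noise_seed`, optionally `bold_csv` with observed data.
#'   \item `sampler`: `n_chains` (default 16, >= 2), `order` (default 5),
#'     `n_samples` (default 1500), `burn_in` (default `n_samples %/% 3`),
#'     `swap_every` (default 1), `target_accept` (default 0.25).
#'   \item `estimators`: list from `ti`, `ame`, `hme` (default all three).
#'   \item `seed`: integer master seed (default 1).
#'   \item `output_dir`: where [run_evidence()] writes its artifacts.
#' }
#'
#' @param path YAML or JSON file.
#' @return A validated, fully resolved configuration (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  resolve_config(raw)
}

#' @rdname load_config
#' @param config a raw configuration list.
#' @export
resolve_config <- function(config) {
  known_top <- c("model", "sampler", "estimators", "seed", "output_dir")
  check_keys(config, known_top, "top level")
  if (is.null(config$model) || is.null(config$model$family))
    stop("config error: model.family is required", call. = FALSE)

  model <- config$model
  if (model$family == "linreg") {
    known <- c("family", "p", "M", "prior_var", "noise_var", "dataset_seed",
               "dir")
    check_keys(model, known, "model (linreg)")
    if (is.null(model$dir)) {
      model$p <- model$p %||% 4L
      model$M <- model$M %||% 100L
      model$prior_var <- model$prior_var %||% 16
      model$noise_var <- model$noise_var %||% 10
      model$dataset_seed <- model$dataset_seed %||% 1L
    }
  } else if (model$family == "dcm") {
    known <- c("family", "fixture", "snr", "noise_seed", "bold_csv",
               "n_scans")
    check_keys(model, known, "model (dcm)")
    model$fixture <- model$fixture %||% "m1"
    if (!model$fixture %in% paste0("m", 1:5))
      stop("config error: model.fixture must be one of m1..m5",
           call. = FALSE)
    model$snr <- model$snr %||% 1
    model$noise_seed <- model$noise_seed %||% 1L
    model$n_scans <- model$n_scans %||% 720L
  } else {
    stop("config error: unknown model.family '", model$family, "'",
         call. = FALSE)
  }

  sampler <- config$sampler %||% list()
  check_keys(sampler, c("n_chains", "order", "n_samples", "burn_in",
                        "swap_every", "target_accept"), "sampler")
  sampler$n_chains <- sampler$n_chains %||% 16L
  if (sampler$n_chains < 2)
    stop("config error: sampler.n_chains must be >= 2", call. = FALSE)
  sampler$order <- sampler$order %||% 5
  sampler$n_samples <- sampler$n_samples %||% 1500L
  sampler$burn_in <- sampler$burn_in %||% (sampler$n_samples %/% 3L)
  sampler$swap_every <- sampler$swap_every %||% 1L
  sampler$target_accept <- sampler$target_accept %||% 0.25

  estimators <- tolower(unlist(config$estimators %||% c("ti", "ame", "hme")))
  bad <- setdiff(estimators, c("ti", "ame", "hme"))
  if (length(bad))
    stop("config error: unknown estimator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  structure(list(model = model, sampler = sampler, estimators = estimators,
                 seed = as.integer(config$seed %||% 1L),
                 output_dir = config$output_dir %||% NULL),
            class = "run_config")
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("config error in ", where, ": unknown key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a resolved configuration back to YAML
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

build_config_model <- function(config) {
  m <- config$model
  if (m$family == "linreg") {
    if (!is.null(m$dir)) return(read_linreg_model(m$dir))
    return(generate_linreg_dataset(m$p, m$M, m$prior_var, m$noise_var,
                                   seed = m$dataset_seed))
  }
  spec <- dcm_fixture_models(n_scans = m$n_scans)[[m$fixture]]
  observed <- if (!is.null(m$bold_csv)) read_bold_csv(m$bold_csv)
  else add_noise_at_snr(integrate_dcm(spec), m$snr,
                        seed = m$noise_seed)$observed
  dcm_model(spec, observed)
}

#' Run a configured evidence estimation end to end
#'
#' Builds the model named by the configuration, runs the population sampler,
#' applies the requested estimators, and (if `output_dir` is set) writes a
#' self-describing output directory: the resolved configuration, the trace
#' (per-temperature draws and log-likelihoods as CSV plus JSON metadata),
#' JSON evidence estimates, the per-temperature expected log-likelihood
#' curve as CSV, and a plain-text log with acceptance rates and the maximum
#' split-half R-hat.
#'
#' @param config a `run_config` (from [load_config()] / [resolve_config()]).
#' @return An `evidence_fit`, invisibly.
#' @export
run_evidence <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- build_config_model(config)
  s <- config$sampler
  fit <- model_evidence(model, methods = config$estimators,
                        n_chains = s$n_chains, order = s$order,
                        n_samples = s$n_samples, burn_in = s$burn_in,
                        seed = config$seed, swap_every = s$swap_every,
                        target_accept = s$target_accept)
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(dir, "config.yaml"))
    write_trace(fit$trace, file.path(dir, "trace"))
    ests <- lapply(fit$estimates, function(e)
      list(method = e$method, lme = e$lme, mc_se = e$mc_se,
           n_samples_used = e$n_samples_used))
    jsonlite::write_json(ests, file.path(dir, "estimates.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(fit$estimates$ti))
      write_evidence_curve_csv(fit$estimates$ti, file.path(dir, "curve.csv"))
    rh <- split_rhat(fit$trace)
    writeLines(c(
      sprintf("model: %s", fit$model_name),
      sprintf("seed: %d", config$seed),
      sprintf("max split R-hat (log-likelihood): %.4f", attr(rh, "max")),
      sprintf("within-chain acceptance: %s",
              paste(sprintf("%.3f", fit$trace$acceptance$within),
                    collapse = " ")),
      sprintf("swap acceptance: %s",
              paste(sprintf("%.3f", fit$trace$acceptance$swap),
                    collapse = " "))),
      file.path(dir, "run.log"))
  }
  invisible(fit)
}

#' Persist / restore a population trace as plain text
#'
#' Writes one CSV of draws per temperature (`draws_###.csv`), the cached
#' log-likelihood and log-prior matrices, and a JSON metadata file (schedule,
#' seed, burn-in, acceptance rates).
#'
#' @param trace a `population_trace`.
#' @param dir output directory.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "population_trace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(trace$draws))
    utils::write.csv(as.data.frame(trace$draws[[j]]),
                     file.path(dir, sprintf("draws_%03d.csv", j)),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(trace$loglik),
                   file.path(dir, "loglik.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(trace$logprior),
                   file.path(dir, "logprior.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(betas = trace$schedule$betas, order = trace$schedule$order,
         burn_in = trace$burn_in, n_samples = trace$n_samples,
         seed = trace$seed, model_name = trace$model_name, dim = trace$dim,
         acceptance = trace$acceptance),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_trace
#' @export
read_trace <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n_beta <- length(meta$betas)
  draws <- lapply(seq_len(n_beta), function(j) {
    m <- as.matrix(utils::read.csv(file.path(dir,
                                             sprintf("draws_%03d.csv", j))))
    dimnames(m) <- NULL
    m
  })
  loglik <- as.matrix(utils::read.csv(file.path(dir, "loglik.csv")))
  logprior <- as.matrix(utils::read.csv(file.path(dir, "logprior.csv")))
  dimnames(loglik) <- dimnames(logprior) <- NULL
  sched <- structure(list(betas = meta$betas, order = meta$order),
                     class = "temperature_schedule")
  structure(
    list(schedule = sched, draws = draws, loglik = loglik,
         logprior = logprior,
         acceptance = list(within = meta$acceptance$within,
                           swap = meta$acceptance$swap),
         burn_in = meta$burn_in, n_samples = meta$n_samples,
         seed = meta$seed, model_name = meta$model_name, dim = meta$dim),
    class = "population_trace")
}
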