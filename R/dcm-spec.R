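#' Default haemodynamic constants
#'
#' The balloon-windkessel observation model is used with its conventional
#' constants: signal decay kappa = 0.64 1/s, autoregulatory feedback
#' gamma = 0.32 1/s, mean transit time tau = 2 s, vessel stiffness
#' alpha = 0.32, resting oxygen extraction rho = 0.32, resting venous blood
#' volume fraction V0 = 0.04, and the 1.5 T field-dependent output constants
#' k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2. These are held fixed (not sampled):
#' keeping the observation model constant isolates inference on the
#' connectivity parameters.
#'
#' @return Named list of haemodynamic constants.
#' @export
dcm_hemo_defaults <- function() {
  rho <- 0.32
  list(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32, rho = rho,
       V0 = 0.04, k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2)
}

#' Specify a dynamic causal model of fMRI
#'
#' A `dcm_spec` bundles the neuronal connectivity of a DCM — endogenous
#' coupling `A` (Hz), input-dependent bilinear modulation `B` (one R x R
#' matrix per input, Hz), driving-input weights `C` (Hz), and
#' activity-dependent nonlinear modulation `D` (one R x R matrix per gating
#' region, Hz) — with the haemodynamic constants, the stimulus time courses
#' and the acquisition parameters (repetition time, number of scans).
#' The structurally nonzero entries of A (off-diagonal), B, C and D define
#' the free parameters when the spec is inverted (see [dcm_model()]); the
#' stored numeric values are the generating values used for simulation.
#'
#' @param A R x R endogenous connectivity matrix; diagonal entries must be
#'   negative (self-inhibition, stability).
#' @param B R x R x n_inputs array (or list of matrices, or NULL for none).
#' @param C R x n_inputs driving-input weight matrix.
#' @param D R x R x R array indexed by gating region (or list, or NULL).
#' @param inputs n_timesteps x n_inputs matrix of stimulus time courses,
#'   piecewise constant at resolution `input_dt`.
#' @param input_dt input sampling interval in seconds (default 0.5 s,
#'   i.e. a 2 Hz sampling rate).
#' @param TR repetition time in seconds.
#' @param n_scans number of acquired volumes.
#' @param hemo haemodynamic constants, see [dcm_hemo_defaults()].
#' @param name model identifier.
#' @return An object of class `dcm_spec`.
#' @export
dcm_spec <- function(A, B = NULL, C, D = NULL, inputs, input_dt = 0.5,
                     TR = 2, n_scans, hemo = dcm_hemo_defaults(),
                     name = "dcm") {
  A <- as.matrix(A)
  R <- nrow(A)
  if (ncol(A) != R) stop("A must be square", call. = FALSE)
  if (any(diag(A) >= 0))
    stop("self-connections (diag of A) must be negative", call. = FALSE)
  C <- as.matrix(C)
  if (nrow(C) != R) stop("C must have one row per region", call. = FALSE)
  nu <- ncol(C)
  B <- as_cube(B, R, nu, "B (one matrix per input)")
  D <- as_cube(D, R, R, "D (one matrix per region)")
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != nu)
    stop("inputs must have one column per input", call. = FALSE)
  n_scans <- as.integer(n_scans)
  if (nrow(inputs) * input_dt < n_scans * TR - 1e-9)
    stop("inputs do not cover the acquisition window (need rows * input_dt",
         " >= n_scans * TR)", call. = FALSE)
  stopifnot(is.list(hemo), all(c("kappa", "gamma", "tau", "alpha", "rho",
                                 "V0", "k1", "k2", "k3") %in% names(hemo)))
  structure(
    list(name = name, n_regions = R, n_inputs = nu, A = A, B = B, C = C,
         D = D, inputs = inputs, input_dt = input_dt, TR = TR,
         n_scans = n_scans, hemo = hemo),
    class = "dcm_spec"
  )
}

as_cube <- function(x, R, nslice, what) {
  if (is.null(x)) return(array(0, dim = c(R, R, nslice)))
  if (is.list(x)) x <- array(unlist(x), dim = c(R, R, length(x)))
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || !all(dim(x) == c(R, R, nslice)))
    stop(what, " must be ", R, " x ", R, " x ", nslice, call. = FALSE)
  x
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("<dcm_spec>", x$name, ":", x$n_regions, "regions,", x$n_inputs,
      "inputs,", x$n_scans, "scans (TR", x$TR, "s)\n")
  cat("  free connectivity entries:",
      length(dcm_param_layout(x)$free_names), "\n")
  invisible(x)
}

#' Block-design stimulus time courses
#'
#' Two boxcar inputs sampled at `1/input_dt` Hz: u1 alternates 40 s on /
#' 40 s off and u2 alternates 60 s on / 60 s off, so their on-phases overlap
#' in a varying pattern over the run — the variation that makes bilinear and
#' nonlinear modulatory effects identifiable.
#'
#' @param n_scans,TR,input_dt acquisition parameters (defaults 720, 2 s,
#'   0.5 s).
#' @return An (n_scans * TR / input_dt) x 2 matrix with columns `u1`, `u2`.
#' @export
dcm_block_inputs <- function(n_scans = 720, TR = 2, input_dt = 0.5) {
  n <- ceiling(n_scans * TR / input_dt)
  t <- (seq_len(n) - 1) * input_dt
  u1 <- as.numeric((t %% 80) < 40)
  u2 <- as.numeric((t %% 120) < 60)
  cbind(u1 = u1, u2 = u2)
}

#' Bundled 3-region example models
#'
#' Five 3-region, two-input DCMs spanning the linear / bilinear / nonlinear
#' model classes, used by the model-recovery experiment. All five share the
#' same endogenous backbone (u1 drives region 1, u2 drives region 2, both
#' upstream regions project to region 3) and differ in how region 3's
#' dynamics are explained:
#' \itemize{
#'   \item m1 — driving inputs and fixed endogenous connections only
#'     (B = D = 0); the "null hypothesis" model.
#'   \item m2 — u2 bilinearly modulates the forward connection
#'     region 1 -> region 3.
#'   \item m3 — u1 bilinearly modulates the forward connection
#'     region 2 -> region 3.
#'   \item m4 — u1 modulates the self-connection of region 3.
#'   \item m5 — nonlinear gating: activity in region 2 gates the
#'     region 1 -> region 3 connection (a D effect).
#' }
#' The numeric connectivity values bundled here are synthetic defaults chosen
#' in the typical range for simulated DCM studies (self-connections -0.5 Hz,
#' forward connections 0.4 Hz, driving inputs 0.25 Hz, modulatory effects
#' 0.6 Hz in magnitude, so that neuronal excursions stay below ~1 and the
#' BOLD response in the low percent range); they are this package's own
#' fixture values, not transcribed from any external study.
#'
#' @param n_scans,TR,input_dt acquisition parameters (defaults: 720 scans,
#'   TR = 2 s, inputs sampled at 2 Hz).
#' @return Named list of five `dcm_spec` objects `m1`..`m5`.
#' @export
dcm_fixture_models <- function(n_scans = 720, TR = 2, input_dt = 0.5) {
  R <- 3; nu <- 2
  u <- dcm_block_inputs(n_scans, TR, input_dt)
  A <- matrix(0, R, R)
  diag(A) <- -0.5
  A[3, 1] <- 0.4
  A[3, 2] <- 0.4
  C <- matrix(0, R, nu)
  C[1, 1] <- 0.25
  C[2, 2] <- 0.25
  mk <- function(name, B = NULL, D = NULL)
    dcm_spec(A, B, C, D, inputs = u, input_dt = input_dt, TR = TR,
             n_scans = n_scans, name = name)

  B2 <- array(0, dim = c(R, R, nu)); B2[3, 1, 2] <- 0.6
  B3 <- array(0, dim = c(R, R, nu)); B3[3, 2, 1] <- 0.6
  B4 <- array(0, dim = c(R, R, nu)); B4[3, 3, 1] <- -0.4
  D5 <- array(0, dim = c(R, R, R)); D5[3, 1, 2] <- 0.6

  list(m1 = mk("m1"),
       m2 = mk("m2", B = B2),
       m3 = mk("m3", B = B3),
       m4 = mk("m4", B = B4),
       m5 = mk("m5", D = D5))
}

#' Free-parameter layout of a DCM specification
#'
#' The parameter vector consumed by [integrate_dcm()], [dcm_log_likelihood()]
#' and the sampler is laid out as: R self-connection parameters (the
#' self-connection of region i is \eqn{-0.5 \exp(a_i)} Hz so it is always
#' negative), the structurally nonzero off-diagonal entries of A, then of B,
#' C and D (column-major order), and finally R per-region log noise
#' precisions.
#'
#' @param spec a `dcm_spec`.
#' @return A list with index vectors into A/B/C/D, the parameter count
#'   `n_par`, prior mean/sd vectors, and human-readable `free_names`.
#' @export
dcm_param_layout <- function(spec) {
  R <- spec$n_regions
  offdiag <- !diag(TRUE, R)
  idx_a <- which(spec$A != 0 & offdiag)
  idx_b <- which(spec$B != 0)
  idx_c <- which(spec$C != 0)
  idx_d <- which(spec$D != 0)
  n_con <- R + length(idx_a) + length(idx_b) + length(idx_c) + length(idx_d)
  n_par <- n_con + R
  nm <- c(paste0("self_", seq_len(R)),
          paste0("A_", idx_a), paste0("B_", idx_b),
          paste0("C_", idx_c), paste0("D_", idx_d),
          paste0("logprec_", seq_len(R)))
  # Priors: N(0, 1/16) on self/off-diagonal/modulatory parameters, N(0, 1/4)
  # on driving inputs, N(log 10, 1) on log noise precisions (dcm_model
  # recenters the latter at the empirical data variance).
  mu <- c(rep(0, n_con), rep(log(10), R))
  sd <- c(rep(0.25, R + length(idx_a) + length(idx_b)),
          rep(0.5, length(idx_c)), rep(0.25, length(idx_d)), rep(1, R))
  list(R = R, idx_a = idx_a, idx_b = idx_b, idx_c = idx_c, idx_d = idx_d,
       n_par = n_par, n_con = n_con, prior_mean = mu, prior_sd = sd,
       free_names = nm)
}

# Build A, B, C, D arrays from a parameter vector (connectivity part only).
dcm_build_matrices <- function(spec, theta, layout = dcm_param_layout(spec)) {
  R <- layout$R
  A <- matrix(0, R, R)
  diag(A) <- -0.5 * exp(theta[seq_len(R)])
  pos <- R
  take <- function(n) {
    out <- theta[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  A[layout$idx_a] <- take(length(layout$idx_a))
  B <- array(0, dim = dim(spec$B)); B[layout$idx_b] <- take(length(layout$idx_b))
  C <- matrix(0, R, spec$n_inputs); C[layout$idx_c] <- take(length(layout$idx_c))
  D <- array(0, dim = dim(spec$D)); D[layout$idx_d] <- take(length(layout$idx_d))
  list(A = A, B = B, C = C, D = D)
}

#' Parameter vector reproducing a spec's stored connectivity
#'
#' Maps the generating matrices of `spec` back onto the free-parameter layout
#' (inverting the \eqn{-0.5\exp(a)} self-connection transform) and appends
#' per-region log noise precisions.
#'
#' @param spec a `dcm_spec`.
#' @param log_prec length-R vector of log noise precisions (default log 10).
#' @return Numeric parameter vector of length `dcm_param_layout(spec)$n_par`.
#' @export
dcm_true_params <- function(spec, log_prec = rep(log(10), spec$n_regions)) {
  layout <- dcm_param_layout(spec)
  c(log(diag(spec$A) / -0.5),
    spec$A[layout$idx_a], spec$B[layout$idx_b],
    spec$C[layout$idx_c], spec$D[layout$idx_d],
    rep_len(log_prec, layout$R))
}

#' Serialize / load a DCM specification
#'
#' `write_dcm_spec()` writes the spec as one YAML document (matrices as
#' nested arrays); `read_dcm_spec()` reconstructs it.
#'
#' @param spec a `dcm_spec`.
#' @param path YAML file path.
#' @export
write_dcm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dcm_spec"))
  doc <- list(name = spec$name, n_regions = spec$n_regions,
              n_inputs = spec$n_inputs,
              A = unclass_mat(spec$A), B = cube_to_list(spec$B),
              C = unclass_mat(spec$C), D = cube_to_list(spec$D),
              inputs = unclass_mat(spec$inputs),
              input_dt = spec$input_dt, TR = spec$TR,
              n_scans = spec$n_scans, hemo = spec$hemo)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_dcm_spec
#' @export
read_dcm_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  R <- doc$n_regions
  tomat <- function(x) do.call(rbind, lapply(x, as.numeric))
  dcm_spec(A = tomat(doc$A),
           B = lapply(doc$B, tomat),
           C = tomat(doc$C),
           D = lapply(doc$D, tomat),
           inputs = tomat(doc$inputs),
           input_dt = doc$input_dt, TR = doc$TR, n_scans = doc$n_scans,
           hemo = doc$hemo, name = doc$name)
}

unclass_mat <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
cube_to_list <- function(a)
  lapply(seq_len(dim(a)[3]), function(k) unclass_mat(a[, , k, drop = TRUE]))
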