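test_that("no drive means exactly baseline output", {
  u <- dcm_block_inputs(n_scans = 40)
  spec <- dcm_spec(A = diag(-0.5, 3), C = matrix(0, 3, 2), inputs = u,
                   n_scans = 40)
  sig <- integrate_dcm(spec)
  expect_true(all(sig == 0))
})

test_that("deleting modulatory terms reproduces the linear model's output", {
  specs <- tiny_dcm_specs()
  m2_stripped <- dcm_spec(specs$m2$A, B = NULL, C = specs$m2$C, D = NULL,
                          inputs = specs$m2$inputs, n_scans = specs$m2$n_scans)
  expect_identical(integrate_dcm(m2_stripped), integrate_dcm(specs$m1))
  m5_stripped <- dcm_spec(specs$m5$A, B = NULL, C = specs$m5$C, D = NULL,
                          inputs = specs$m5$inputs, n_scans = specs$m5$n_scans)
  expect_identical(integrate_dcm(m5_stripped), integrate_dcm(specs$m1))
})

test_that("one-region neuronal trajectory matches the closed-form linear ODE", {
  a <- -0.4; cc <- 0.3
  dt <- 0.5
  n_scans <- 30
  nbin <- n_scans * 2 * 2 # cover window
  tgrid <- (seq_len(nbin) - 1) * dt
  u <- matrix(as.numeric(tgrid >= 5 & tgrid < 20), ncol = 1)
  spec <- dcm_spec(A = matrix(a), C = matrix(cc), inputs = u,
                   n_scans = n_scans)
  out <- integrate_dcm(spec, method = "rk4", substeps = 8,
                       return_states = TRUE)
  # x(t) = int_0^t e^{a(t-s)} c u(s) ds, u a square pulse on [5, 20)
  closed_form <- function(t) {
    if (t <= 5) return(0)
    t1 <- min(t, 20)
    x_on <- cc / (-a) * (1 - exp(a * (t1 - 5)))
    if (t <= 20) x_on else x_on * exp(a * (t - 20))
  }
  times <- seq_len(nrow(out$states) - 1) * (dt / 1) # state after each bin
  xs <- out$states[-1, 1]
  ref <- vapply(times, closed_form, 0)
  expect_lt(max(abs(xs - ref)), 1e-3)
})

test_that("noise injection hits the requested SNR", {
  specs <- dcm_fixture_models() # full 720-scan series for a tight SD band
  sig <- integrate_dcm(specs$m1)
  dat <- add_noise_at_snr(sig, snr = 1, seed = 42)
  ratio <- apply(dat$observed - dat$signal, 2, sd) / apply(sig, 2, sd)
  expect_true(all(ratio > 0.93 & ratio < 1.07))
  hi <- add_noise_at_snr(sig, snr = 1e9, seed = 42)
  expect_lt(max(abs(hi$observed - sig)) / max(abs(sig)), 1e-6)
  expect_error(add_noise_at_snr(matrix(1, 10, 2), 1), "zero variance")
  expect_error(add_noise_at_snr(sig, -1), "snr")
  # determinism
  expect_identical(add_noise_at_snr(sig, 1, seed = 7)$observed,
                   add_noise_at_snr(sig, 1, seed = 7)$observed)
})

test_that("zero residuals give the Gaussian normalizing constant", {
  specs <- tiny_dcm_specs()
  spec <- specs$m1
  layout <- dcm_param_layout(spec)
  theta <- dcm_true_params(spec, log_prec = rep(0, 3)) # unit noise variance
  pred <- integrate_dcm(spec, theta)
  ll <- dcm_log_likelihood(spec, theta, pred)
  expect_equal(ll, -(spec$n_scans * 3 / 2) * log(2 * pi), tolerance = 1e-10)
})

test_that("log-likelihood scales quadratically in the residuals", {
  specs <- tiny_dcm_specs()
  spec <- specs$m1
  theta <- dcm_true_params(spec, log_prec = c(0.3, -0.1, 0.2))
  pred <- integrate_dcm(spec, theta)
  set.seed(3)
  r <- matrix(rnorm(length(pred), 0, 0.2), nrow(pred))
  ll0 <- dcm_log_likelihood(spec, theta, pred)
  ll1 <- dcm_log_likelihood(spec, theta, pred + r)
  ll2 <- dcm_log_likelihood(spec, theta, pred + 2 * r)
  quad <- ll0 - ll1 # the original quadratic penalty
  expect_equal(ll0 - ll2, 4 * quad, tolerance = 1e-8)
})

test_that("likelihood at the truth beats a perturbed self-connection", {
  # one-region linear DCM, 100 noise realizations at SNR = 1
  dt <- 0.5; n_scans <- 120
  tgrid <- (seq_len(n_scans * 4) - 1) * dt
  u <- matrix(as.numeric((tgrid %% 60) < 30), ncol = 1)
  spec <- dcm_spec(A = matrix(-0.5), C = matrix(0.25), inputs = u,
                   n_scans = n_scans)
  sig <- integrate_dcm(spec)
  truth <- dcm_true_params(spec)
  pert <- truth
  pert[1] <- log((0.5 + 0.5) / 0.5) # self-connection moved by -0.5 Hz
  wins <- 0L
  for (s in 1:100) {
    obs <- add_noise_at_snr(sig, 1, seed = s)$observed
    lp <- log(1 / (apply(sig, 2, sd))^2)
    tt <- truth; tt[length(tt)] <- lp
    pp <- pert; pp[length(pp)] <- lp
    wins <- wins + (dcm_log_likelihood(spec, tt, obs) >
                      dcm_log_likelihood(spec, pp, obs))
  }
  expect_gte(wins, 95)
})

test_that("fixture models are wired as documented and integrate cleanly", {
  specs <- dcm_fixture_models()
  expect_true(all(specs$m1$B == 0) && all(specs$m1$D == 0))
  expect_true(all(specs$m2$D == 0) && any(specs$m2$B != 0))
  expect_true(all(specs$m3$D == 0) && any(specs$m3$B != 0))
  expect_true(all(specs$m4$D == 0) && any(specs$m4$B != 0))
  expect_true(any(specs$m5$D != 0) && all(specs$m5$B == 0))
  for (s in specs) {
    sig <- integrate_dcm(s)
    expect_true(all(is.finite(sig)))
    expect_true(all(apply(sig, 2, sd) > 0))
  }
})

test_that("halving the RK4 step leaves the solution unchanged to < 1e-3 RMS", {
  for (s in dcm_fixture_models(n_scans = 180)) {
    a <- integrate_dcm(s, method = "rk4", substeps = 1)
    b <- integrate_dcm(s, method = "rk4", substeps = 2)
    expect_lt(sqrt(mean((a - b)^2)), 1e-3)
  }
})

test_that("default Euler stepping tracks RK4 well below the noise scale", {
  for (s in dcm_fixture_models(n_scans = 180)) {
    a <- integrate_dcm(s)
    b <- integrate_dcm(s, method = "rk4", substeps = 2)
    expect_lt(sqrt(mean((a - b)^2)), 0.1 * sd(a))
  }
})

test_that("integration is deterministic and the true-parameter map is exact", {
  spec <- tiny_dcm_specs()$m5
  expect_identical(integrate_dcm(spec), integrate_dcm(spec))
  expect_identical(integrate_dcm(spec, dcm_true_params(spec)),
                   integrate_dcm(spec))
})

test_that("unstable connectivity raises a divergence error; likelihood maps it to -Inf", {
  u <- dcm_block_inputs(n_scans = 60)
  D <- array(0, dim = c(1, 1, 1)); D[1, 1, 1] <- 5 # quadratic self-excitation
  spec <- dcm_spec(A = matrix(-0.2), C = matrix(2), D = D,
                   inputs = u[, 1, drop = FALSE], n_scans = 60)
  expect_error(integrate_dcm(spec), class = "powerpost_divergence")
  theta <- dcm_true_params(spec)
  expect_identical(dcm_log_likelihood(spec, theta, matrix(0, 60, 1)), -Inf)
})

test_that("DCM specs round-trip through YAML", {
  spec <- tiny_dcm_specs(n_scans = 20)$m5
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dcm_spec(spec, path)
  spec2 <- read_dcm_spec(path)
  expect_equal(spec2$A, spec$A)
  expect_equal(spec2$B, spec$B)
  expect_equal(spec2$D, spec$D)
  expect_equal(integrate_dcm(spec2), integrate_dcm(spec))
})

test_that("BOLD CSV round-trips with region headers", {
  sig <- integrate_dcm(tiny_dcm_specs(n_scans = 20)$m1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bold_csv(sig, path)
  expect_equal(read_bold_csv(path), unname(sig), tolerance = 1e-12)
  header <- readLines(path, n = 1)
  expect_match(header, "region_1")
})
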