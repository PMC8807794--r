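test_that("trapezoid quadrature is exact for constant and linear integrands", {
  betas <- power_schedule(9, 5)$betas
  # constant curve
  tr <- synthetic_trace(betas, matrix(-4.2, 50, length(betas)))
  expect_equal(ti_estimate(tr)$lme, -4.2, tolerance = 1e-12)
  # two-point schedule
  tr2 <- synthetic_trace(c(0, 1), cbind(rep(0, 10), rep(2, 10)))
  expect_equal(ti_estimate(tr2)$lme, 1)
  # linear in beta on an irregular schedule
  set.seed(2)
  b <- sort(c(0, runif(6), 1))
  tr3 <- synthetic_trace(b, matrix(b, 20, length(b), byrow = TRUE))
  expect_equal(ti_estimate(tr3)$lme, 0.5, tolerance = 1e-12)
  # affine 3 - 2 beta likewise exact
  tr4 <- synthetic_trace(b, matrix(3 - 2 * b, 20, length(b), byrow = TRUE))
  expect_equal(ti_estimate(tr4)$lme, 2, tolerance = 1e-12)
})

test_that("the optional Simpson rule is exact on quadratics", {
  set.seed(8)
  b <- sort(c(0, runif(5), 1)) # 7 points: three triples' worth of intervals
  quad <- 1 - 3 * b + 2 * b^2
  tr <- synthetic_trace(b, matrix(quad, 10, length(b), byrow = TRUE))
  expect_equal(ti_estimate(tr, rule = "simpson")$lme,
               1 - 3 / 2 + 2 / 3, tolerance = 1e-12)
  # and agrees with the trapezoid on linear curves
  tr2 <- synthetic_trace(b, matrix(b, 10, length(b), byrow = TRUE))
  expect_equal(ti_estimate(tr2, rule = "simpson")$lme, 0.5,
               tolerance = 1e-12)
})

test_that("invalid traces are rejected with informative errors", {
  tr <- synthetic_trace(c(0, 0.5), matrix(0, 10, 2))
  expect_error(ti_estimate(tr), "beta = 0 and beta = 1")
  tr2 <- synthetic_trace(c(0, 1), cbind(rep(-Inf, 10), rep(1, 10)))
  expect_error(ti_estimate(tr2), "non-finite E_MC")
  tr3 <- synthetic_trace(c(0, 1), matrix(0, 0, 2))
  expect_error(ti_estimate(tr3), "no retained samples")
})

test_that("all three estimators return exactly c on a degenerate model", {
  cval <- -7.25
  m <- constant_model(cval, 2L)
  fit <- model_evidence(m, n_chains = 4, n_samples = 50, burn_in = 10,
                        seed = 3)
  expect_equal(fit$estimates$ti$lme, cval, tolerance = 1e-12)
  expect_equal(fit$estimates$ame$lme, cval, tolerance = 1e-12)
  expect_equal(fit$estimates$hme$lme, cval, tolerance = 1e-12)
})

test_that("AME of a flat likelihood is zero for any sample size", {
  m <- flat_model(2L)
  expect_equal(ame_estimate(m, 1, seed = 1)$lme, 0)
  expect_equal(ame_estimate(m, 500, seed = 2)$lme, 0)
})

test_that("HME reduces to the harmonic mean of the likelihoods", {
  e <- hme_estimate(c(log(1), log(3)))
  expect_equal(e$lme, log(1.5), tolerance = 1e-12)
  expect_equal(hme_estimate(rep(-2.5, 20))$lme, -2.5)
  expect_error(hme_estimate(c(-Inf, -Inf)), "finite")
})

test_that("accuracy curve is flat at zero for a flat likelihood", {
  tr <- synthetic_trace(power_schedule(5, 5)$betas, matrix(0, 30, 5))
  ac <- accuracy_curve(tr)
  expect_true(all(ac$accuracy == 0))
  expect_true(attr(ac, "monotone"))
})

test_that("free-energy decomposition matches the conjugate oracle at beta = 1", {
  m <- generate_linreg_dataset(2, 40, seed = 14)
  tr <- run_population_mcmc(m, power_schedule(16, 5), n_samples = 2000,
                            burn_in = 700, seed = 15)
  n_beta <- length(tr$schedule$betas)
  dec0 <- decompose_free_energy(tr, 1)
  expect_equal(dec0$neg_free_energy, 0)
  expect_equal(dec0$accuracy_term, 0)
  expect_equal(dec0$kl_term, 0)

  dec1 <- decompose_free_energy(tr, n_beta)
  analytic <- linreg_log_evidence(m)
  expect_lt(abs(dec1$neg_free_energy - analytic), 0.5)
  post <- linreg_posterior(m)
  kl_oracle <- gaussian_kl(post$mean, post$precision,
                           rep(0, 2), m$prior_precision)
  expect_lt(abs(dec1$kl_term - kl_oracle), 0.5)

  # KL term nonnegative (up to MC error) along the whole path
  e <- ti_estimate(tr)
  for (j in seq_len(n_beta)) {
    dec <- decompose_free_energy(tr, j)
    w <- 2 * sqrt(sum(e$curve$se[seq_len(j)]^2))
    expect_gte(dec$kl_term, -2 * w - 1e-8)
  }
})

test_that("TI tracks the analytic evidence on a conjugate model", {
  m <- generate_linreg_dataset(4, 100, seed = 7)
  fit <- model_evidence(m, n_chains = 16, order = 5, n_samples = 1500,
                        burn_in = 500, seed = 11)
  expect_lt(abs(fit$estimates$ti$lme - linreg_log_evidence(m)), 0.5)
  expect_true(is.finite(fit$estimates$ti$mc_se))
  expect_equal(nrow(fit$estimates$ti$curve), 16)
})

test_that("estimate objects serialize to JSON and CSV", {
  tr <- synthetic_trace(c(0, 0.5, 1), matrix(rnorm(30), 10, 3))
  e <- ti_estimate(tr)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_evidence_json(e, jpath)
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(j$lme, e$lme, tolerance = 1e-12)
  expect_equal(j$method, "TI")
  write_evidence_curve_csv(e, cpath)
  expect_equal(nrow(read.csv(cpath)), 3)
})
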