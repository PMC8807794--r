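test_that("power schedules follow the power rule with exact endpoints", {
  expect_equal(power_schedule(2, 3)$betas, c(0, 1))
  expect_equal(power_schedule(5, 1)$betas, c(0, 0.25, 0.5, 0.75, 1))
  s64 <- power_schedule(64, 5)$betas
  expect_equal(s64[2], (1 / 63)^5)
  expect_equal(s64[33], (32 / 63)^5)
  expect_equal(s64[c(1, 64)], c(0, 1))
  expect_true(all(diff(s64) > 0))
  expect_error(power_schedule(1), "n_chains")
  expect_error(power_schedule(8, 0), "order")
})

test_that("a null proposal is always accepted and beta = 0 ignores the likelihood", {
  m <- constant_model(-5, 1L)
  pp <- power_posterior(m, 0.5)
  set.seed(1)
  st <- mh_step(0.3, pp, proposal_scale = 0)
  expect_true(st$accepted) # identical proposal, delta = 0
  expect_equal(st$state, 0.3)

  # two models identical except for the likelihood constant: at beta = 0 the
  # chains evolve identically under the same RNG stream
  run_one <- function(c) {
    m <- constant_model(c, 1L)
    pp <- power_posterior(m, 0)
    set.seed(42)
    x <- 0
    for (i in 1:50) x <- mh_step(x, pp, 0.8)$state
    x
  }
  expect_identical(run_one(-1e6), run_one(1e6))
})

test_that("MH chain targets a standard normal when the likelihood is flat", {
  m <- flat_model(1L)
  pp <- power_posterior(m, 1)
  set.seed(7)
  n <- 8000
  x <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- mh_step(cur, pp, 1.5)$state
    x[i] <- cur
  }
  se_mean <- sd(x) / sqrt(ess(x))
  expect_lt(abs(mean(x)), 3 * se_mean)
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / ess(x)))
})

test_that("swap log ratio matches its closed form and degenerate cases", {
  expect_equal(swap_log_ratio(0.2, 0.4, -10, -5), -1)
  expect_equal(swap_log_ratio(0.3, 0.3, -10, -5), 0)
  expect_equal(swap_log_ratio(0.2, 0.4, -7, -7), 0)
  expect_equal(swap_log_ratio(0.4, 0.2, -10, -5), 1) # antisymmetric in order
})

test_that("beta = 1 chain reproduces the conjugate posterior moments", {
  m <- generate_linreg_dataset(2, 30, seed = 6)
  tr <- run_population_mcmc(m, power_schedule(8, 5), n_samples = 3000,
                            burn_in = 1000, seed = 17)
  post <- linreg_posterior(m)
  j <- length(tr$schedule$betas)
  X <- tr$draws[[j]]
  Sig <- solve(post$precision)
  for (d in 1:2) {
    se <- sd(X[, d]) / sqrt(ess(X[, d]))
    expect_lt(abs(mean(X[, d]) - post$mean[d]), 3 * se)
    expect_lt(abs(sd(X[, d]) / sqrt(Sig[d, d]) - 1), 0.2)
  }
})

test_that("beta = 0 chain is indistinguishable from direct prior draws", {
  m <- generate_linreg_dataset(2, 25, seed = 3)
  tr <- run_population_mcmc(m, power_schedule(4, 5), n_samples = 2000,
                            burn_in = 100, seed = 23)
  X <- tr$draws[[1]]
  for (d in 1:2) {
    ks <- suppressWarnings(stats::ks.test(X[, d], "pnorm", 0, 4))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("swap moves leave the beta = 1 stationary distribution unchanged", {
  m <- generate_linreg_dataset(1, 20, seed = 8)
  post <- linreg_posterior(m)
  run <- function(swap_every) {
    tr <- run_population_mcmc(m, power_schedule(4, 5), n_samples = 3000,
                              burn_in = 800, seed = 31,
                              swap_every = swap_every)
    tr$draws[[4]][, 1]
  }
  a <- run(1)
  b <- run(1e9) # swaps never fire
  se <- sqrt(sd(a)^2 / ess(a) + sd(b)^2 / ess(b))
  expect_lt(abs(mean(a) - mean(b)), 3.5 * se)
  expect_lt(abs(mean(a) - post$mean), 3.5 * se)
})

test_that("expected log-likelihood is nondecreasing in beta up to MC error", {
  m <- generate_linreg_dataset(4, 60, seed = 12)
  tr <- run_population_mcmc(m, power_schedule(8, 5), n_samples = 1500,
                            burn_in = 500, seed = 9)
  ac <- accuracy_curve(tr)
  expect_true(attr(ac, "monotone"))
})

test_that("identical seeds give bit-identical traces", {
  m <- generate_linreg_dataset(2, 15, seed = 5)
  a <- run_population_mcmc(m, power_schedule(4, 5), 200, 50, seed = 77)
  b <- run_population_mcmc(m, power_schedule(4, 5), 200, 50, seed = 77)
  expect_identical(a$draws, b$draws)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$acceptance, b$acceptance)
})

test_that("a zero-length run returns a valid empty trace", {
  m <- generate_linreg_dataset(2, 15, seed = 5)
  tr <- run_population_mcmc(m, power_schedule(4, 5), 0, 10, seed = 1)
  expect_s3_class(tr, "population_trace")
  expect_equal(tr$n_samples, 0L)
  expect_equal(nrow(tr$loglik), 0L)
  expect_equal(nrow(tr$draws[[1]]), 0L)
})

test_that("cached log-likelihoods cohere with the stored draws", {
  m <- generate_linreg_dataset(2, 15, seed = 5)
  tr <- run_population_mcmc(m, power_schedule(4, 5), 50, 20, seed = 13)
  for (j in seq_along(tr$draws))
    for (k in c(1, 25, 50))
      expect_equal(tr$loglik[k, j], m$log_likelihood(tr$draws[[j]][k, ]),
                   tolerance = 1e-12)
})

test_that("Gelman-Rubin statistic behaves across regimes", {
  expect_equal(gelman_rubin(list(rep(2, 10), rep(2, 10))), 1)
  set.seed(4)
  expect_lt(gelman_rubin(list(rnorm(5000), rnorm(5000))), 1.01)
  expect_gt(gelman_rubin(list(rnorm(1000, 0), rnorm(1000, 10))), 3)
  expect_error(gelman_rubin(list(rnorm(10))), "2 segments")
  expect_error(gelman_rubin(list(rnorm(3), rnorm(3))), "length >= 4")
  expect_error(gelman_rubin(list(rnorm(4), rnorm(5))), "equal length")
})

test_that("split R-hat summarizes the per-temperature log-likelihood traces", {
  K <- 100
  ll <- cbind(rnorm(K), rnorm(K))
  tr <- synthetic_trace(c(0, 1), ll)
  r <- split_rhat(tr)
  expect_length(r, 2)
  # for iid halves R-hat sits near its sqrt((n-1)/n) floor
  expect_true(all(r >= sqrt(49 / 50) - 1e-8))
  expect_true(all(r < 1.2))
  expect_equal(attr(r, "max"), max(r))
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(21)
  x <- rnorm(4000)
  expect_gt(ess(x), 2000)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  expect_lt(ess(ar), ess(x) / 3)
  expect_equal(ess(rep(1, 100)), 100)
})
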