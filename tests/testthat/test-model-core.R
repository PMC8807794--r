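test_that("analytic evidence matches a dense 1-D quadrature of prior x likelihood", {
  m <- linreg_model(matrix(c(1, 1), 2, 1), c(1, -1), matrix(1), diag(2))
  f <- function(th) vapply(th, function(t)
    exp(m$log_likelihood(t) + m$log_prior(t)), 0)
  q <- stats::integrate(f, -10, 10, rel.tol = 1e-10)$value
  expect_equal(linreg_log_evidence(m), log(q), tolerance = 1e-8)
})

test_that("analytic evidence matches the marginal Gaussian density for p = 2", {
  set.seed(5)
  p <- 2; M <- 15
  X <- matrix(rnorm(M * p), M, p)
  y <- rnorm(M, 0, 2)
  Pp <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  Pe <- diag(1 / runif(M, 0.5, 2))
  m <- linreg_model(X, y, Pp, Pe)
  # independent route: y ~ N(0, X Pp^-1 X' + Pe^-1)
  S <- X %*% solve(Pp) %*% t(X) + solve(Pe)
  oracle <- -0.5 * (M * log(2 * pi) +
                      as.numeric(determinant(S)$modulus) +
                      drop(t(y) %*% solve(S, y)))
  expect_equal(linreg_log_evidence(m), oracle, tolerance = 1e-6)
})

test_that("all-zero design decouples parameters from data", {
  set.seed(2)
  M <- 8
  y <- rnorm(M)
  Pe <- diag(1 / 10, M)
  m <- linreg_model(matrix(0, M, 2), y, diag(2), Pe)
  fit_only <- sum(dnorm(y, 0, sqrt(10), log = TRUE))
  expect_equal(linreg_log_evidence(m), fit_only, tolerance = 1e-10)
  post <- linreg_posterior(m)
  expect_equal(post$mean, c(0, 0))
  expect_equal(post$precision, diag(2))
})

test_that("posterior moments follow the conjugate update", {
  m <- linreg_model(matrix(1), 2, matrix(1), matrix(1))
  post <- linreg_posterior(m)
  expect_equal(post$precision, matrix(2))
  expect_equal(post$mean, 1)
})

test_that("evidence is invariant under joint row permutation of X, y, noise", {
  set.seed(9)
  m0 <- generate_linreg_dataset(3, 20, seed = 4)
  perm <- sample(20)
  m1 <- linreg_model(m0$design[perm, ], m0$data[perm],
                     m0$prior_precision, m0$noise_precision[perm, perm])
  expect_equal(linreg_log_evidence(m1), linreg_log_evidence(m0),
               tolerance = 1e-10)
})

test_that("posterior precision stays SPD for random SPD inputs", {
  set.seed(11)
  for (i in 1:5) {
    p <- sample(2:5, 1); M <- 12
    m <- linreg_model(matrix(rnorm(M * p), M, p), rnorm(M),
                      crossprod(matrix(rnorm(p * p), p)) + diag(p),
                      diag(runif(M, 0.2, 3)))
    ev <- eigen(linreg_posterior(m)$precision, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("invalid precision matrices and shape mismatches are rejected", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(linreg_model(X, rnorm(3), matrix(c(1, 2, 2, 1), 2), diag(3)),
               "positive definite")
  expect_error(linreg_model(X, rnorm(3), diag(2), -diag(3)),
               "positive definite")
  expect_error(linreg_model(X, rnorm(4), diag(2), diag(3)), "nrow")
  expect_error(linreg_model(X, rnorm(3), diag(3), diag(3)), "2 x 2")
})

test_that("ANOVA block design assigns excess rows to the last cell", {
  m <- generate_linreg_dataset(2, 4, seed = 1)
  expect_equal(unname(m$design),
               rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  m2 <- generate_linreg_dataset(3, 100, seed = 1)
  expect_equal(unname(colSums(m2$design)), c(33, 33, 34))
  expect_true(all(rowSums(m2$design) == 1))
})

test_that("dataset generation is deterministic and validates p <= M", {
  a <- generate_linreg_dataset(4, 30, seed = 99)
  b <- generate_linreg_dataset(4, 30, seed = 99)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "theta_true"), attr(b, "theta_true"))
  expect_error(generate_linreg_dataset(10, 5), "p <= M")
})

test_that("linreg models round-trip through CSV + JSON", {
  m <- generate_linreg_dataset(3, 10, seed = 2)
  dir <- withr::local_tempdir()
  write_linreg_model(m, dir)
  m2 <- read_linreg_model(dir)
  expect_equal(m2$design, m$design)
  expect_equal(m2$data, m$data, tolerance = 1e-12)
  expect_equal(m2$prior_precision, m$prior_precision)
  expect_equal(linreg_log_evidence(m2), linreg_log_evidence(m),
               tolerance = 1e-10)
})
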