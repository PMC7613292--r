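test_that("path estimates reproduce exact noiseless constructions", {
  X <- as.numeric(1:8)
  e <- 0.5 * c(1, -1, -1, 1, 1, -1, -1, 1)  # orthogonal to X by construction
  M <- 2 * X + e
  Y <- 3 * M + X
  est <- fit_paths(X, M, Y)
  expect_equal(est$a, 2, tolerance = 1e-12)
  expect_equal(est$b, 3, tolerance = 1e-12)
  expect_equal(est$c_prime, 1, tolerance = 1e-12)
  expect_equal(est$c, 7, tolerance = 1e-12)
  expect_equal(est$ab, 6, tolerance = 1e-12)

  # Y a pure function of X: the mediator's partial slope is exactly zero
  set.seed(81)
  M2 <- X + rnorm(8)
  est2 <- fit_paths(X, M2, 2 * X)
  expect_equal(est2$b, 0, tolerance = 1e-12)
  expect_equal(est2$ab, 0, tolerance = 1e-12)

  expect_error(fit_paths(rep(1, 5), rnorm(5), rnorm(5)), "non-constant")
  expect_error(fit_paths(X, 2 * X, Y), "collinear")
  expect_error(fit_paths(X[1:3], M[1:3], Y[1:3]), ">= 4")
})

test_that("the OLS decomposition c = c' + ab holds on arbitrary samples", {
  set.seed(82)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    X <- rnorm(n); M <- 0.5 * X + rnorm(n); Y <- rnorm(n) + M - X
    est <- fit_paths(X, M, Y)
    expect_lt(abs(est$c - est$c_prime - est$ab), 1e-10)
  }
})

test_that("BCa reduces to the percentile interval when z0 = 0 and accel = 0", {
  set.seed(83)
  boots <- rnorm(2000, 1, 0.3)
  plain <- optimbias:::bca_interval(boots, 1, z0 = 0, accel = 0)
  expect_equal(plain, quantile(boots, c(0.025, 0.975), names = FALSE),
               tolerance = 1e-12)
})

test_that("bootstrap mediation is seed-reproducible with bootstrap-independent point estimates", {
  set.seed(84)
  n <- 50
  X <- runif(n, 9, 18)
  M <- 0.1 + 0.03 * (X - 9) + rnorm(n, 0, 0.1)
  Y <- 1 - 0.9 * M + rnorm(n, 0, 0.3)
  r1 <- bca_bootstrap_mediation(X, M, Y, n_boot = 500, seed = 9)
  r2 <- bca_bootstrap_mediation(X, M, Y, n_boot = 500, seed = 9)
  expect_identical(r1$paths, r2$paths)
  r3 <- bca_bootstrap_mediation(X, M, Y, n_boot = 1000, seed = 10)
  expect_equal(r1$paths$estimate, r3$paths$estimate, tolerance = 1e-12)
  expect_equal(r1$paths$estimate[r1$paths$path == "ab"],
               unlist(fit_paths(X, M, Y)["ab"]), ignore_attr = TRUE)
  # every bootstrap draw satisfies the decomposition identity too
  expect_lt(max(abs(r1$boots[, "c"] - r1$boots[, "c_prime"] -
                      r1$boots[, "ab"])), 1e-10)
  expect_true(all(r1$paths$p_boot >= 1 / 500 & r1$paths$p_boot <= 1))
  expect_error(bca_bootstrap_mediation(X, M, Y, n_boot = 10), ">= 100")
})

test_that("the subject-table wrapper maps age, negative rate and bias onto X, M, Y", {
  set.seed(85)
  d <- data.frame(age_years = runif(40, 9, 18))
  d$alpha_neg <- 0.05 + 0.03 * (d$age_years - 9) + rnorm(40, 0, 0.08)
  d$optimism_bias <- 1.5 - 1.2 * d$alpha_neg + rnorm(40, 0, 0.3)
  res <- mediate_age_bias(d, n_boot = 300, seed = 3)
  direct <- fit_paths(d$age_years, d$alpha_neg, d$optimism_bias)
  expect_equal(res$paths$estimate[res$paths$path == "a"], direct$a)
  expect_error(mediate_age_bias(d[, 1:2]), "columns")
})
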