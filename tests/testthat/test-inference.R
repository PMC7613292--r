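test_that("the truncated-Gaussian likelihood matches an independent oracle", {
  # single trial at the mode: -log[phi(0) / (Phi(3) - Phi(-3))]
  rec <- make_records(4.0, 4L)
  p <- rw_params(4, 0.3, 0.3, 1)
  expect_equal(negative_log_likelihood(p, rec),
               -log(dnorm(0) / (pnorm(3) - pnorm(-3))), tolerance = 1e-10)

  set.seed(31)
  for (rep in 1:10) {
    sub <- sim_subject(mu0 = runif(1, 2, 6), alpha_pos = runif(1),
                       alpha_neg = runif(1), xi = runif(1, 0.2, 1),
                       seed = rep)
    pp <- rw_params(runif(1, 1, 7), runif(1), runif(1), runif(1, 0.1, 2),
                    kappa = runif(1, 0, 0.3), lambda = runif(1, 0, 0.3))
    expect_equal(negative_log_likelihood(pp, sub), nll_oracle(pp, sub),
                 tolerance = 1e-8)
  }
})

test_that("NLL grows as reports move away from the latent prediction", {
  p <- rw_params(5, 0.4, 0.1, 0.6)
  sched <- generate_schedule(30, seed = 14)
  lat <- predict_beliefs(p, sched$reward_magnitude)[1:30]
  rec <- make_records(lat, sched$reward_magnitude)
  base <- negative_log_likelihood(p, rec)
  for (shift in c(0.3, 0.8, 1.5)) {
    pert <- rec
    pert$reward_belief <- pmin(pmax(lat + shift, 1), 7)
    expect_gt(negative_log_likelihood(p, pert), base)
  }
  # moving a single report to the scale bound strictly increases the NLL
  pert <- rec
  pert$reward_belief[10] <- 7
  expect_gt(negative_log_likelihood(p, pert), base)
  expect_error(negative_log_likelihood(p, rec[0, ]), "non-empty")
  expect_error(rw_params(4, 0.3, 0.3, xi = 0), "positive")
})

test_that("near-noiseless data is recovered to high precision", {
  sched <- generate_schedule(200, seed = 41)
  truth <- rw_params(5.2, 0.45, 0.15, 0.02)
  rec <- simulate_agent(truth, sched, seed = 42)
  fit <- fit_subject(rec, model_spec("V4"), seed = 43)
  expect_lt(abs(fit$params$mu0 - 5.2), 0.02)
  expect_lt(abs(fit$params$alpha_pos - 0.45), 0.02)
  expect_lt(abs(fit$params$alpha_neg - 0.15), 0.02)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$nll + 2 * fit$n_free)
  expect_equal(fit$bic, 2 * fit$nll + fit$n_free * log(fit$n_obs))
})

test_that("fitting refuses insufficient data and flags flat likelihoods", {
  rec <- sim_subject(seed = 8)
  expect_error(fit_subject(rec[1:5, ], model_spec("V4")), "at least")
  const <- make_records(rep(4, 20), rep(4L, 20))
  expect_warning(fit <- fit_subject(const, model_spec("V4"), seed = 2),
                 "flat")
  expect_true(fit$flat_likelihood)
  expect_true(fit$converged)
})

test_that("nested variants are ordered in best NLL", {
  for (seed in c(3, 17)) {
    rec <- sim_subject(mu0 = 5.5, alpha_pos = 0.5, alpha_neg = 0.1, xi = 0.5,
                       seed = seed)
    nll <- vapply(c("V1", "V3", "V4"), function(v)
      fit_subject(rec, model_spec(v), seed = seed)$nll, numeric(1))
    expect_lte(nll[["V4"]], nll[["V3"]] + 1e-3)
    expect_lte(nll[["V3"]], nll[["V1"]] + 1e-3)
  }
})

test_that("BIC comparison penalises parameters and counts wins", {
  # same fit quality, different complexity: the simpler variant must win
  nll <- 50; n <- 40
  tab <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 2),
    variant_id = rep(c("lean", "rich"), 2),
    bic = rep(c(2 * nll + 2 * log(n), 2 * nll + 4 * log(n)), 2))
  cmp <- compare_models(tab)
  expect_equal(cmp$best_variant, "lean")
  expect_equal(unname(cmp$best_count["lean"]), 2L)
  expect_equal(sum(cmp$best_count), 2L)
  one <- data.frame(subject_id = "s1", variant_id = "only", bic = 10)
  expect_equal(compare_models(one)$best_variant, "only")
  expect_error(compare_models(tab[-1, ]), "every variant")
})

test_that("parameter recovery improves with more trials and less noise", {
  sampler <- list(xi = function(n) rep(0.8, n))
  hard <- suppressWarnings(
    parameter_recovery(model_spec("V4"), n_agents = 25, n_trials = 30,
                       param_sampler = sampler, n_restarts = 10, seed = 51))
  sampler$xi <- function(n) rep(0.1, n)
  easy <- suppressWarnings(
    parameter_recovery(model_spec("V4"), n_agents = 25, n_trials = 150,
                       param_sampler = sampler, n_restarts = 10, seed = 51))
  r_hard <- hard$summary$pearson_r[hard$summary$parameter == "alpha_neg"]
  r_easy <- easy$summary$pearson_r[easy$summary$parameter == "alpha_neg"]
  expect_gt(r_easy, r_hard)
  expect_gt(r_easy, 0.9)
  # constant sampler: undefined correlation, flagged
  expect_warning(
    deg <- parameter_recovery(model_spec("V4"), n_agents = 4, n_trials = 20,
                              param_sampler = list(
                                mu0 = function(n) rep(4, n)),
                              n_restarts = 4, seed = 5),
    "undefined")
  expect_true(is.na(
    deg$summary$pearson_r[deg$summary$parameter == "mu0"]))
})

test_that("two well-separated variants are told apart by model recovery", {
  sampler <- list(xi = function(n) rep(0.15, n),
                  alpha_pos = function(n) runif(n, 0.5, 0.7),
                  alpha_neg = function(n) runif(n, 0.02, 0.1),
                  mu0 = function(n) runif(n, 4.5, 6.5))
  mr <- model_recovery(list(model_spec("V1"), model_spec("V4")),
                       n_agents_per_spec = 6, n_trials = 60,
                       param_sampler = sampler, n_restarts = 8, seed = 61)
  expect_equal(rowSums(mr$confusion), c(generating.V1 = 1, generating.V4 = 1),
               ignore_attr = TRUE)
  expect_gt(mr$confusion["V1", "V1"], mr$confusion["V1", "V4"])
  expect_gt(mr$confusion["V4", "V4"], mr$confusion["V4", "V1"])
  expect_error(model_recovery(list(model_spec("V1")), 2), "two variants")
})
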