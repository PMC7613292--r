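test_that("the valence-split update applies the rate matching the PE sign", {
  expect_equal(rw_update(4.0, 7, 0.5, 0.1), 5.5)  # delta = +3, positive rate
  expect_equal(rw_update(4.0, 1, 0.5, 0.1), 3.7)  # delta = -3, negative rate
  expect_equal(rw_update(4.0, 4, 0.5, 0.1), 4.0)  # zero prediction error
  expect_error(rw_update(0.5, 4, 0.3, 0.3), "\\[1, 7\\]")
  expect_error(rw_update(4, 9, 0.3, 0.3), "1..7")
  expect_error(rw_update(4, 4, 1.2, 0.3), "\\[0, 1\\]")
})

test_that("latent trajectories follow the recursion and stay on the scale", {
  p <- rw_params(mu0 = 4, alpha_pos = 0.5, alpha_neg = 0.1, xi = 0.5)
  expect_equal(predict_beliefs(p, c(7L, 1L)), c(4.0, 5.5, 5.05))
  # no learning: belief pinned at the prior
  p0 <- rw_params(mu0 = 3.2, alpha_pos = 0, alpha_neg = 0, xi = 0.5)
  expect_true(all(predict_beliefs(p0, sample(1:7, 30, TRUE)) == 3.2))
  expect_error(predict_beliefs(p, integer(0)), "non-empty")
  expect_error(predict_beliefs(p, c(3L, 8L)), "1..7")

  set.seed(21)
  for (rep in 1:25) {
    p <- rw_params(mu0 = runif(1, 1, 7), alpha_pos = runif(1),
                   alpha_neg = runif(1), xi = 0.5,
                   kappa = runif(1, 0, 0.5), lambda = runif(1, 0, 0.5))
    out <- sample(1:7, 60, TRUE)
    lat <- predict_beliefs(p, out, failures = rbinom(60, 1, 0.3))
    expect_true(all(lat >= 1 & lat <= 7))
  }
})

test_that("tying the two learning rates reproduces the single-rate model", {
  set.seed(4)
  out <- sample(1:7, 50, TRUE)
  a <- 0.37
  tied <- predict_beliefs(rw_params(4.5, a, a, 0.5), out)
  single <- Reduce(function(b, o) rw_update(b, o, a, a), out,
                   accumulate = TRUE, init = 4.5)
  expect_identical(tied, as.numeric(single))
})

test_that("the asymptotic oracle gives the affine fixed point", {
  expect_equal(asymptotic_bias_oracle(0.4, 0.1, 1, 7), 5.8)
  expect_equal(asymptotic_bias_oracle(0.3, 0.3, 1, 7), 4.0)
  expect_equal(asymptotic_bias_oracle(0.1, 0.4, 1, 7), 2.2)
  expect_error(asymptotic_bias_oracle(0, 0, 1, 7), "positive")
  expect_error(asymptotic_bias_oracle(0.2, 0.2, 7, 1), "r_lo")
})

test_that("simulated agents are reproducible, clipped, and noiseless in the xi -> 0 limit", {
  sched <- generate_schedule(40, seed = 12)
  p <- rw_params(5, 0.4, 0.1, 0.8)
  a <- simulate_agent(p, sched, seed = 5)
  b <- simulate_agent(p, sched, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$reward_belief >= 1 & a$reward_belief <= 7))
  expect_true(all(a$success %in% 0:1))
  expect_true(all(a$success == as.integer(
    a$effort_exerted_fraction >= a$effort_threshold)))
  tiny <- simulate_agent(rw_params(5, 0.4, 0.1, 1e-8), sched, seed = 5)
  expect_equal(tiny$reward_belief, tiny$latent_belief, tolerance = 1e-6)
  expect_error(simulate_agent(p, sched, effort_policy = "nope"), "policy")
})

test_that("optimistic, pessimistic and balanced learners bracket the outcome mean", {
  set.seed(6)
  out <- sample(c(1L, 7L), 4000, TRUE)
  mean_tail <- function(ap, an)
    mean(predict_beliefs(rw_params(4, ap, an, 0.5), out)[2001:4000])
  expect_gt(mean_tail(0.4, 0.1), 4)
  expect_lt(mean_tail(0.1, 0.4), 4)
  expect_equal(mean_tail(0.3, 0.3), 4, tolerance = 0.15)
})
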