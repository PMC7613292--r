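test_that("optimism bias is mean belief minus mean displayed reward", {
  rec <- make_records(c(3, 4, 5), c(3L, 4L, 5L))
  s <- summarize_subject(rec)
  expect_equal(s$optimism_bias, 0)
  expect_equal(s$success_rate, 1)
  rec2 <- make_records(rep(7, 10), rep(1L, 10))
  expect_equal(summarize_subject(rec2)$optimism_bias, 6)
  expect_error(summarize_subject(rec[0, ]), "non-empty")

  # an optimistic learner on symmetric {1,7} outcomes sits above the mean
  set.seed(71)
  out <- sample(c(1L, 7L), 2000, TRUE)
  lat <- predict_beliefs(rw_params(4, 0.4, 0.1, 0.5), out)[1:2000]
  rec3 <- make_records(lat, out)
  expect_gt(summarize_subject(rec3)$optimism_bias, 0)
  expect_lt(abs(summarize_subject(rec3)$mean_belief -
                  asymptotic_bias_oracle(0.4, 0.1, 1, 7)), 0.3)
})

test_that("noiseless lagged-belief construction is recovered exactly", {
  set.seed(72)
  n <- 60
  rewards <- sample(1:7, n, TRUE)
  success <- rbinom(n, 1, 0.7)
  fail_code <- ifelse(success == 1, -1, 1)
  beliefs <- numeric(n)
  beliefs[1] <- 4
  for (t in 2:n)
    beliefs[t] <- 2.30 + 0.34 * rewards[t - 1] + 0.09 * fail_code[t - 1] +
      0.20 * beliefs[t - 1]
  rec <- make_records(beliefs, rewards, success)
  beta <- belief_regression(rec)
  expect_equal(unname(beta),
               c(2.30, 0.34, 0.09, 0.20), tolerance = 1e-8)
})

test_that("the regression equals lm on random designs and handles degeneracy", {
  set.seed(73)
  for (rep in 1:10) {
    rec <- sim_subject(seed = 100 + rep)
    beta <- belief_regression(rec, include_previous_effort = TRUE)
    n <- nrow(rec)
    df <- data.frame(y = rec$reward_belief[-1],
                     pr = rec$reward_magnitude[-n],
                     pf = ifelse(rec$success[-n] == 1, -1, 1),
                     pb = rec$reward_belief[-n],
                     pe = rec$effort_exerted_fraction[-n])
    expect_equal(unname(beta), unname(coef(lm(y ~ pr + pf + pb + pe, df))),
                 tolerance = 1e-8)
  }
  # all-success subject: failure column constant, dropped, reported NA
  rec <- sim_subject(seed = 1)
  rec$success <- 1L
  rec$effort_exerted_fraction <- pmax(rec$effort_exerted_fraction,
                                      rec$effort_threshold)
  expect_warning(beta <- belief_regression(rec), "previous_failure")
  expect_true(is.na(beta["previous_failure"]))
  expect_false(anyNA(beta[c("intercept", "previous_reward",
                            "previous_belief")]))
  # beliefs identical to rewards make previous_belief duplicate
  # previous_reward: rank-deficient
  dup <- make_records(as.numeric(rec$reward_magnitude),
                      rec$reward_magnitude)
  expect_error(suppressWarnings(belief_regression(dup)), "rank-deficient")
  expect_error(belief_regression(rec[1:4, ]), "too few")
})

test_that("group-level coefficient tests follow the one-sample t formula", {
  b <- data.frame(x = c(-1, 0, 1))
  res <- group_level_coefficient_test(b)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(group_level_coefficient_test(data.frame(x = c(2, 2, 2))),
               "zero variance")
  set.seed(74)
  bb <- data.frame(x = rnorm(99, 0.3, 0.2))
  res2 <- group_level_coefficient_test(bb)
  expect_equal(res2$t, mean(bb$x) / (sd(bb$x) / sqrt(99)), tolerance = 1e-10)
  expect_equal(res2$df, 98)
})

test_that("one-way ANOVA gives F, partial eta squared and the t^2 identity", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  res <- one_way_anova(vals, grp)
  expect_equal(res$F, 0)
  expect_equal(res$partial_eta_sq, 0)
  set.seed(75)
  v2 <- rnorm(30)
  g2 <- rep(c("a", "b"), each = 15)
  res2 <- one_way_anova(v2, g2)
  t2 <- pairwise_t(v2[g2 == "a"], v2[g2 == "b"], welch_policy = "student")
  expect_equal(res2$F, t2$t^2, tolerance = 1e-8)
  expect_equal(res2$p, t2$p, tolerance = 1e-8)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("pairwise t-tests report Welch df and pooled-SD Cohen's d", {
  same <- pairwise_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  d1 <- pairwise_t(c(-1, 0, 1), c(0, 1, 2), welch_policy = "student")
  expect_equal(d1$cohens_d, 1)
  set.seed(76)
  a <- rnorm(20, sd = 1); b <- rnorm(12, sd = 3)
  w <- pairwise_t(a, b, welch_policy = "welch")
  va <- var(a) / 20; vb <- var(b) / 12
  df_ws <- (va + vb)^2 / (va^2 / 19 + vb^2 / 11)  # Welch-Satterthwaite
  expect_equal(w$df, df_ws, tolerance = 1e-8)
  auto <- pairwise_t(a, b, welch_policy = "auto")
  expect_true(auto$welch)
  expect_error(pairwise_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("learning asymmetry correlates with bias; partial r removes an age confound", {
  subj <- sprintf("s%02d", 1:40)
  set.seed(77)
  asym <- runif(40, -0.2, 0.5)
  fits <- data.frame(subject_id = subj, alpha_pos = 0.3 + asym,
                     alpha_neg = 0.3)
  summaries <- data.frame(subject_id = subj, optimism_bias = 2 * asym,
                          age_years = runif(40, 9, 18))
  res <- asymmetry_bias_correlation(fits, summaries)
  expect_equal(res$pearson_r, 1, tolerance = 1e-10)

  # both variables driven by age only: raw r large, partial r near zero
  age <- seq(9, 18, length.out = 60)
  fits2 <- data.frame(subject_id = sprintf("t%02d", 1:60),
                      alpha_pos = 0.6 - 0.02 * age + rnorm(60, 0, 0.01),
                      alpha_neg = 0.1)
  summaries2 <- data.frame(subject_id = fits2$subject_id,
                           optimism_bias = 3 - 0.15 * age + rnorm(60, 0, 0.03),
                           age_years = age)
  res2 <- asymmetry_bias_correlation(fits2, summaries2)
  expect_gt(res2$pearson_r, 0.9)
  expect_lt(abs(res2$partial_r_controlling_age), 0.35)
  expect_error(asymmetry_bias_correlation(
    data.frame(subject_id = subj, alpha_pos = 0.3, alpha_neg = 0.3),
    summaries), "constant")
})
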